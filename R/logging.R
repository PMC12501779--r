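# Structured logging. Messages go to stderr as "<time> [LEVEL] msg";
# the threshold is controlled by options(brcaIS.log_level=).

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("brcaIS.log_level", "info")
  options(brcaIS.log_level = level)
  invisible(old)
}

bs_log <- function(level, msg, ...) {
  threshold <- .log_levels[[getOption("brcaIS.log_level", "info")]]
  if (.log_levels[[level]] < threshold) return(invisible(NULL))
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%OS2"),
                  toupper(level), sprintf(msg, ...))
  message(line)
  invisible(NULL)
}
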