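# Classed conditions so the CLI can map failures to exit statuses:
# usage errors -> 2, runtime I/O errors -> 1, configuration errors -> 1.

slp_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "slp_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_usage <- function(message) slp_stop("slp_usage_error", message)
stop_input <- function(message) slp_stop("slp_input_error", message)
stop_output <- function(message) slp_stop("slp_output_error", message)
stop_config <- function(message) slp_stop("slp_config_error", message)
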