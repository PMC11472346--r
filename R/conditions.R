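# Classed conditions so the command-line wrapper can map failures to exit
# codes (config -> 2, data -> 3, numeric -> 4) without string matching.

stop_config <- function(msg, ...) {
  stop(structure(class = c("porewalk_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("porewalk_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_numeric <- function(msg, ...) {
  stop(structure(class = c("porewalk_numeric_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
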