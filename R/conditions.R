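# Classed conditions so callers (and the CLI) can distinguish config errors,
# data/schema errors, and degenerate numerics without parsing messages.

stop_gait <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gait_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# error taxonomy:
#   gait_config_error  - bad configuration / parameters (CLI exit 2)
#   gait_io_error      - unreadable input               (CLI exit 3)
#   gait_schema_error  - parseable but wrong shape      (CLI exit 3)
#   gait_length_error  - series too short               (CLI exit 3)
#   gait_param_error   - invalid numeric arguments      (CLI exit 2)
#   gait_degenerate_error - degenerate numerics (singular fit, zero variance)
#   gait_data_error    - other data-level failure       (CLI exit 3)

`%||%` <- function(a, b) if (is.null(a)) b else a
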