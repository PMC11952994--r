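# Condition helpers. Undefined acoustic features are signalled with a
# dedicated class so extraction can convert them to explicit missing values
# (never silent zeros); validation failures carry their own class so I/O and
# label problems are distinguishable from programming errors.

stop_undefined_feature <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("vocalmct_undefined_feature", "error"),
                      call = call))
}

stop_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("vocalmct_validation_error", "error"),
                      call = call))
}

is_undefined_feature <- function(e) inherits(e, "vocalmct_undefined_feature")

# Evaluate an expression, mapping undefined-feature conditions to NA_real_.
na_if_undefined <- function(expr) {
  tryCatch(expr, vocalmct_undefined_feature = function(e) NA_real_)
}
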