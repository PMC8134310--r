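# Structured error conditions so the command-line wrapper can map failure
# classes onto exit codes (config 2, schema 3, degenerate data 4).

.cond_stop <- function(class, ...) {
  stop(structure(class = c(class, "biopsynav_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.config_error <- function(...) .cond_stop("biopsynav_config_error", ...)
.schema_error <- function(...) .cond_stop("biopsynav_schema_error", ...)
.degenerate_error <- function(...) .cond_stop("biopsynav_degenerate_error", ...)
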