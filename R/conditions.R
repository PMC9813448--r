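# Classed conditions. Every error raised by this package carries class
# "pheno_error"; validation failures (bad values, malformed scales, schema
# violations) additionally carry "pheno_validation_error", I/O failures
# "pheno_io_error". The CLI maps these to exit codes 2 and 3.

pheno_stop <- function(message, class, call = sys.call(-1), data = NULL) {
  cond <- structure(
    class = c(class, "pheno_error", "error", "condition"),
    list(message = message, call = call, data = data)
  )
  stop(cond)
}

stop_validation <- function(message, subclass = NULL, data = NULL) {
  pheno_stop(message, c(subclass, "pheno_validation_error"),
             call = sys.call(-1), data = data)
}

stop_io <- function(message, subclass = NULL, data = NULL) {
  pheno_stop(message, c(subclass, "pheno_io_error"),
             call = sys.call(-1), data = data)
}

is_pheno_error <- function(x) inherits(x, "pheno_error")
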