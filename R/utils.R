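# internal helpers: typed conditions shared across the package

msipError <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "msipError", "error", "condition"),
    list(message = message, call = call)
  ))
}

msipWarning <- function(message, class) {
  warning(structure(
    class = c(class, "msipWarning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# scalar numeric check; NA not allowed
assertScalarNumeric <- function(x, name, positive = FALSE, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    msipError(sprintf("'%s' must be a single non-missing number", name),
              "msipValidationError")
  if (positive && (if (strict) x <= 0 else x < 0))
    msipError(sprintf("'%s' must be %s", name,
                      if (strict) "strictly positive" else "non-negative"),
              "msipValidationError")
  invisible(x)
}

# restore RNG state on exit so seeded internals do not perturb the caller
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
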