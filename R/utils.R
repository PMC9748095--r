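# Internal numeric helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# log(1 + exp(x)) without overflow for large |x|
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# elementwise log(exp(a) + exp(b)); stable when both arguments are very
# negative (zero-inflation mass vs Poisson zero mass)
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# build a model matrix from stored column names; "(Intercept)" maps to a
# column of ones and "a:b" to the elementwise product of its parents
matrix_from_names <- function(col_names, data) {
  n <- nrow(data)
  cols <- lapply(col_names, function(nm) {
    if (nm == "(Intercept)") return(rep(1, n))
    if (grepl(":", nm, fixed = TRUE)) {
      parents <- strsplit(nm, ":", fixed = TRUE)[[1]]
      miss <- setdiff(parents, names(data))
      if (length(miss))
        stop("columns not found for interaction '", nm, "': ",
             paste(miss, collapse = ", "))
      return(Reduce(`*`, lapply(parents, function(p) as.numeric(data[[p]]))))
    }
    if (!nm %in% names(data)) stop("column not found in data: '", nm, "'")
    as.numeric(data[[nm]])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- col_names
  if (anyNA(X)) {
    bad <- col_names[apply(X, 2, anyNA)]
    stop("missing values in design columns: ", paste(bad, collapse = ", "))
  }
  X
}
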