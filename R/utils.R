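#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats as.formula binomial coef confint lm glm logLik median
#'   plogis qnorm rbinom rlnorm rnorm runif sd setNames AIC BIC vcov pnorm
#' @importFrom utils adist head
NULL

# Round half-up (commercial rounding) -- base round() rounds half to even,
# which disagrees with how registry percentages are conventionally displayed.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Fold diacritics to ASCII and lower-case; used for sponsor/title matching.
# stringi's transliterator is locale-independent (iconv //TRANSLIT is not).
fold_ascii <- function(x) {
  tolower(stringi::stri_trans_general(x, "Latin-ASCII"))
}

# Split a ";"-joined multi-value field into a trimmed character vector.
split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  v <- stringr::str_trim(strsplit(x, ";", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

join_multi <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) == 0) NA_character_ else paste(x, collapse = ";")
}

# Percentage of a count over a denominator, full precision.
pct_of <- function(n, denom) ifelse(denom > 0, 100 * n / denom, NA_real_)

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Run an expression with a locally seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, expr) {
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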