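# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed per named stream, so e.g. adding persons never
# perturbs the weather stream. Kept below 2^31 - 1.
sub_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 99991L
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

# Strict ISO-8601 date parsing; errors carry the table name and row number so
# malformed CDM exports are diagnosable.
parse_iso_date <- function(x, table, column) {
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonblank <- !is.na(x) & nzchar(x)
  out[nonblank] <- as.Date(x[nonblank], format = "%Y-%m-%d")
  bad <- nonblank & is.na(out)
  if (any(bad)) {
    stop(sprintf("table '%s', column '%s': unparseable date '%s' at row %d",
                 table, column, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  if (any(!nonblank)) {
    stop(sprintf("table '%s', column '%s': missing date at row %d",
                 table, column, which(!nonblank)[1]), call. = FALSE)
  }
  out
}

check_enum <- function(x, allowed, table, column) {
  x <- as.character(x)
  bad <- !(x %in% allowed)
  if (any(bad)) {
    stop(sprintf("table '%s', column '%s': unknown value '%s' at row %d (allowed: %s)",
                 table, column, x[which(bad)[1]], which(bad)[1],
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  x
}

# Normalise an ICD-10 code for prefix matching: upper case, dot removed.
normalize_icd10 <- function(code) gsub(".", "", toupper(trimws(code)), fixed = TRUE)

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
  invisible(x)
}
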