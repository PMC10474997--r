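# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
# The four month-to-month transition codes, in fixed display order:
# stay zero, persist, enter, disappear.
TRANSITION_CODES <- c("--", "++", "-+", "+-")

# Lookup from (state at t, state at t+1) to a transition code;
# index = 2 * state_t + state_t1 + 1.
.transition_lookup <- c("--", "-+", "+-", "++")

.default_month_labels <- c("May", "June", "July")

# Evaluate `code` under a locally-set RNG seed, restoring the caller's
# RNG state afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.check_prob <- function(x, name, allow_vector = TRUE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L)) {
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  x
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, as.character(line), msg), call. = FALSE)
}

# Month labels <-> ordinals. Accepts integers ("1", 1) or names drawn
# from `labels` (default May/June/July, the breeding-season design).
month_ordinal <- function(x, labels = .default_month_labels) {
  if (is.numeric(x)) return(as.integer(x))
  x <- as.character(x)
  out <- suppressWarnings(as.integer(x))
  named <- is.na(out)
  idx <- match(tolower(x[named]), tolower(labels))
  if (anyNA(idx)) {
    stop(sprintf("unknown month token(s): %s",
                 paste(unique(x[named][is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  out[named] <- idx
  out
}

month_label <- function(ord, labels = .default_month_labels) {
  ord <- as.integer(ord)
  ifelse(ord >= 1L & ord <= length(labels), labels[pmin(pmax(ord, 1L), length(labels))],
         as.character(ord))
}
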