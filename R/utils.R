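# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Classed error constructors so callers can condition on failure mode.
stop_lightphen <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "lightphen_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x)

# Round half away from zero to `digits` decimals (base round() is half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Compact letter display from a symmetric logical "differs" relation.
# Insert-and-absorb: start from one column holding every group; each
# significantly different pair splits any column containing both; columns that
# are subsets of another are absorbed.
compact_letters <- function(groups, differs) {
  stopifnot(is.matrix(differs), nrow(differs) == length(groups))
  cols <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      if (!isTRUE(differs[i, j])) next
      a <- groups[i]; b <- groups[j]
      hit <- vapply(cols, function(col) a %in% col && b %in% col, logical(1))
      if (!any(hit)) next
      new_cols <- list()
      for (k in seq_along(cols)) {
        if (hit[k]) {
          new_cols <- c(new_cols, list(setdiff(cols[[k]], a)),
                        list(setdiff(cols[[k]], b)))
        } else {
          new_cols <- c(new_cols, cols[k])
        }
      }
      # absorb duplicates / subsets
      keep <- rep(TRUE, length(new_cols))
      for (k in seq_along(new_cols)) {
        for (m in seq_along(new_cols)) {
          if (k != m && keep[m] && all(new_cols[[k]] %in% new_cols[[m]]) &&
              (length(new_cols[[k]]) < length(new_cols[[m]]) || k > m)) {
            keep[k] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  labs <- vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
           collapse = "")
  }, character(1))
  names(labs) <- groups
  labs
}

treatment_levels <- c("shade", "ambient", "supplemental")
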