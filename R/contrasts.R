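#' Compact letter display from a significance graph
#'
#' Assigns letters to factor levels so that two levels share a letter if and
#' only if they were not declared significantly different. Uses the
#' insert-and-absorb algorithm: start from one group holding all levels,
#' split groups containing both members of each significant pair, then drop
#' groups contained in another.
#'
#' @param levels character vector of level names.
#' @param significant logical matrix (levels x levels), TRUE where the pair is
#'   significantly different; only the upper triangle is used.
#' @return named character vector of letter strings, one per level.
#' @export
letter_display <- function(levels, significant) {
  k <- length(levels)
  if (k == 0) return(character(0))
  groups <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!isTRUE(significant[i, j])) next
      new_groups <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb: drop groups that are subsets of another group
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) {
        for (b in seq_along(new_groups)) {
          if (a != b && keep[b] &&
              all(new_groups[[a]] %in% new_groups[[b]]) &&
              !(all(new_groups[[b]] %in% new_groups[[a]]) && a < b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      groups <- new_groups[keep]
    }
  }
  # order groups by their smallest member so letters read in level order
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  letters_out <- stats::setNames(rep("", k), levels)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    letters_out[idx] <- paste0(letters_out[idx], letters[g])
  }
  letters_out
}

# All pairwise Wald z contrasts among a set of level effects.
# effects: named vector of level effects (reference coded as 0 is fine);
# vcv: matching variance-covariance matrix (zero rows/cols for a reference).
pairwise_wald_contrasts <- function(effects, vcv, alpha = 0.05,
                                    adjust = "holm") {
  lv <- names(effects)
  k <- length(lv)
  if (k < 2) stop("need at least two levels to contrast")
  pairs <- utils::combn(k, 2)
  est <- se <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    est[m] <- effects[i] - effects[j]
    v <- vcv[i, i] + vcv[j, j] - 2 * vcv[i, j]
    se[m] <- sqrt(max(v, 0))
  }
  z <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = adjust)
  sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    sig[i, j] <- sig[j, i] <- p_adj[m] < alpha
  }
  contrasts <- data.frame(
    level_a = lv[pairs[1, ]],
    level_b = lv[pairs[2, ]],
    estimate = est,
    std_error = se,
    z = z,
    p_value = p,
    p_adjusted = p_adj,
    stringsAsFactors = FALSE
  )
  structure(
    list(contrasts = contrasts,
         letters = letter_display(lv, sig),
         alpha = alpha,
         adjust = adjust),
    class = "cause_contrasts"
  )
}

#' @export
print.cause_contrasts <- function(x, ...) {
  cat(sprintf("Pairwise Wald contrasts (%s-adjusted, alpha = %g)\n",
              x$adjust, x$alpha))
  print(x$contrasts, row.names = FALSE, digits = 4)
  cat("Letter display (levels sharing a letter are not significantly different):\n")
  print(x$letters)
  invisible(x)
}
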