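#' Match predicted to ground-truth instances
#'
#' Greedy one-to-one matching by descending point overlap: the predicted /
#' truth instance pair sharing the most points is matched first, then the
#' next among the remaining ids, and so on. Unmatched predicted instances
#' later score against an empty truth set (precision 0).
#'
#' @param pred integer vector of predicted instance ids.
#' @param truth integer vector of ground-truth instance ids, same length.
#' @return named integer vector mapping predicted id -> truth id (as
#'   character names); only matched predictions appear.
#' @export
match_instances <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tab <- table(pred, truth)
  ov <- as.data.frame(tab, stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0L, , drop = FALSE]
  ov <- ov[order(-ov$Freq, ov$pred, ov$truth), , drop = FALSE]
  map <- integer(0)
  used_t <- character(0)
  for (i in seq_len(nrow(ov))) {
    p <- ov$pred[i]; t <- ov$truth[i]
    if (p %in% names(map) || t %in% used_t) next
    map[p] <- as.integer(t)
    used_t <- c(used_t, t)
  }
  map
}

organ_score <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' Score a predicted segmentation against ground truth
#'
#' Point-wise per-organ precision / recall / F1 after [match_instances()],
#' plus plant-level means: the plant precision (recall) is the mean of the
#' per-organ precisions (recalls), and the plant micro-F1 is the harmonic
#' mean of those two means (not the mean of per-organ F1 values). Score
#' rows cover every ground-truth instance (zero scores when unmatched) and
#' every unmatched predicted instance (precision 0, counting its points as
#' false positives), so over-segmentation lowers the plant means.
#'
#' @inheritParams match_instances
#' @return a `plant_score`: list with `per_organ` (data frame: one row per
#'   scored organ), `p_p`, `r_p`, `f_p`, and `n_o` (number of scored
#'   organs).
#' @export
score_plant <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (length(unique(truth)) < 1L) stop("truth has no instances", call. = FALSE)
  map <- match_instances(pred, truth)
  rows <- list()
  for (t in sort(unique(truth))) {
    p_id <- names(map)[map == t]
    in_t <- truth == t
    in_p <- if (length(p_id)) pred == as.integer(p_id[1L]) else rep(FALSE, length(pred))
    sc <- organ_score(sum(in_t & in_p), sum(!in_t & in_p), sum(in_t & !in_p))
    rows[[length(rows) + 1L]] <- c(list(truth_id = t,
                                        pred_id = if (length(p_id)) as.integer(p_id[1L]) else NA_integer_),
                                   sc)
  }
  for (p in setdiff(unique(pred), as.integer(names(map)))) {
    sc <- organ_score(0L, sum(pred == p), 0L)
    rows[[length(rows) + 1L]] <- c(list(truth_id = NA_integer_, pred_id = p), sc)
  }
  per_organ <- do.call(rbind, lapply(rows, as.data.frame))
  p_p <- mean(per_organ$precision)
  r_p <- mean(per_organ$recall)
  f_p <- if (p_p + r_p > 0) 2 * p_p * r_p / (p_p + r_p) else 0
  structure(list(per_organ = per_organ, p_p = p_p, r_p = r_p, f_p = f_p,
                 n_o = nrow(per_organ)),
            class = "plant_score")
}

#' @export
print.plant_score <- function(x, ...) {
  cat(sprintf("<plant_score> %d organs: precision %.3f, recall %.3f, micro-F1 %.3f\n",
              x$n_o, x$p_p, x$r_p, x$f_p))
  invisible(x)
}
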