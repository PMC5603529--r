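#' Colocalization distance threshold from the average endosome diameter
#'
#' Two puncta are called colocalized when their centres of mass lie closer
#' than the average endosome diameter. This computes that threshold as the
#' mean equivalent-disk diameter (`2 * sqrt(area / pi)`) over the query
#' channel's regions.
#'
#' @param regions_ch1 a [segment_endosomes()] result for the query channel.
#' @return Threshold distance in pixels.
#' @export
coloc_threshold <- function(regions_ch1) {
  stopifnot(inherits(regions_ch1, "LabeledRegions"))
  if (!nrow(regions_ch1$regions)) stop("no regions to derive a threshold from")
  mean(regions_ch1$regions$eq_diameter_px)
}

#' Centre-of-mass nearest-neighbour colocalization
#'
#' For every query (channel-1) centroid, finds the Euclidean nearest
#' channel-2 centroid; the object is colocalized when that distance is
#' strictly less than the threshold. Matching is directional (channel 1
#' into channel 2) and many-to-one: several queries may share a partner.
#'
#' @param regions_ch1 query channel segmentation.
#' @param regions_ch2 partner channel segmentation.
#' @param threshold matching distance in pixels; defaults to
#'   [coloc_threshold()] of the query channel.
#' @return A `ColocResult`: list with `n_query`, `n_matched`, `percent`,
#'   `threshold`, `direction` and per-object `nearest_distance` (pixels).
#' @export
colocalization_fraction <- function(regions_ch1, regions_ch2,
                                    threshold = coloc_threshold(regions_ch1)) {
  stopifnot(inherits(regions_ch1, "LabeledRegions"),
            inherits(regions_ch2, "LabeledRegions"))
  q <- regions_ch1$regions
  p <- regions_ch2$regions
  if (!nrow(q)) stop("no query regions")
  if (!nrow(p)) {
    warning("no partner regions; colocalization is 0%")
    nd <- rep(Inf, nrow(q))
  } else {
    d2 <- outer(q$cx, p$cx, "-")^2 + outer(q$cy, p$cy, "-")^2
    nd <- sqrt(apply(d2, 1, min))
  }
  matched <- nd < threshold
  structure(list(n_query = nrow(q), n_matched = sum(matched),
                 percent = 100 * mean(matched), threshold = threshold,
                 direction = "ch1->ch2", nearest_distance = nd),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("<ColocResult> %d/%d colocalized (%.1f%%) at threshold %.2f px (%s)\n",
              x$n_matched, x$n_query, x$percent, x$threshold, x$direction))
  invisible(x)
}

#' Compare colocalization between pulse and chase conditions
#'
#' Summarizes per-cell colocalization percentages for two conditions and
#' tests their difference with a pooled-variance two-tailed Student's
#' t-test.
#'
#' @param results_pulse,results_chase lists of `ColocResult` (one per
#'   cell/field), or numeric vectors of percentages.
#' @return List with per-condition `mean`, `sd`, `n` and the t-test
#'   `p_value` plus the full `htest` object.
#' @export
pulse_chase_coloc_compare <- function(results_pulse, results_chase) {
  pct <- function(r) {
    if (is.numeric(r)) return(r)
    vapply(r, function(x) x$percent, numeric(1))
  }
  a <- pct(results_pulse); b <- pct(results_chase)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 results per condition")
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(pulse = list(mean = mean(a), sd = stats::sd(a), n = length(a)),
       chase = list(mean = mean(b), sd = stats::sd(b), n = length(b)),
       p_value = tt$p.value, test = tt)
}

#' Write a colocalization result to disk
#'
#' Per-object nearest distances as CSV and the summary as JSON.
#'
#' @param result a `ColocResult`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_coloc_result <- function(result, prefix) {
  stopifnot(inherits(result, "ColocResult"))
  p1 <- paste0(prefix, "_distances.csv")
  utils::write.csv(data.frame(object = seq_len(result$n_query),
                              nearest_distance_px = result$nearest_distance,
                              matched = result$nearest_distance < result$threshold),
                   p1, row.names = FALSE)
  p2 <- paste0(prefix, "_summary.json")
  jsonlite::write_json(result[c("n_query", "n_matched", "percent",
                                "threshold", "direction")],
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(distances = p1, summary = p2))
}
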