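# Copy-number-aware controls: merge adjacent same-state segments, exclude
# islands in lost regions, per-chromosome island density by copy-number
# state, and the Mann-Whitney comparison of those densities.

#' Merge adjacent same-state copy-number segments
#'
#' Neighbors with identical state and a gap strictly below `max_gap_bp`
#' are merged, with the gap absorbed into the merged segment. Segments of
#' different state never merge. Input segments must not overlap.
#'
#' @param segments data.frame chrom/start/end/state.
#' @param max_gap_bp merge threshold (strict `<`).
#' @return merged segments, sorted.
#' @export
merge_cna <- function(segments, max_gap_bp = 1e6) {
  s <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  if (nrow(s) > 1) {
    same <- s$chrom[-1] == s$chrom[-nrow(s)]
    if (any(same & s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping CNA segments")
  }
  out <- list()
  for (i in seq_len(nrow(s))) {
    cur <- s[i, ]
    if (length(out)) {
      prev <- out[[length(out)]]
      if (prev$chrom == cur$chrom && prev$state == cur$state &&
          cur$start - prev$end < max_gap_bp) {
        out[[length(out)]]$end <- max(prev$end, cur$end)
        next
      }
    }
    out[[length(out) + 1]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude islands whose midpoint lies in a lost region
#'
#' @param islands data.frame with chrom/start/end.
#' @param segments merged CNA segments.
#' @return list with `retained` (islands kept), `excluded_count` and
#'   `excluded_fraction` (of all input islands).
#' @export
exclude_lost <- function(islands, segments) {
  loss <- segments[segments$state == "loss", , drop = FALSE]
  mid <- interval_midpoint(islands$start, islands$end)
  in_loss <- rep(FALSE, nrow(islands))
  for (i in seq_len(nrow(loss)))
    in_loss <- in_loss | (islands$chrom == loss$chrom[i] &
                          mid >= loss$start[i] & mid < loss$end[i])
  list(retained = islands[!in_loss, , drop = FALSE],
       excluded_count = sum(in_loss),
       excluded_fraction = if (nrow(islands)) mean(in_loss) else 0)
}

#' Island density per chromosome per copy-number state
#'
#' For each chromosome and state in {gain, CNLOH, neutral}, the number of
#' islands with midpoint in that state's footprint divided by the footprint
#' in Mb. The neutral footprint is the chromosome minus all event segments
#' (loss included, since loss-region islands are excluded upstream).
#' Chromosomes with zero footprint for a state contribute no value.
#'
#' @param islands data.frame with chrom/start/end (lost-region islands
#'   already excluded).
#' @param segments merged CNA segments.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data.frame chrom/state/footprint_mb/n_islands/density.
#' @export
density_by_state <- function(islands, segments, chrom_lengths) {
  mid <- interval_midpoint(islands$start, islands$end)
  rows <- list()
  for (chrom in names(chrom_lengths)) {
    seg_c <- segments[segments$chrom == chrom, , drop = FALSE]
    mid_c <- mid[islands$chrom == chrom]
    for (state in c("gain", "CNLOH", "neutral")) {
      if (state == "neutral") {
        fp_bp <- chrom_lengths[[chrom]] - sum(seg_c$end - seg_c$start)
        n <- length(mid_c)
        for (i in seq_len(nrow(seg_c)))
          n <- n - sum(mid_c >= seg_c$start[i] & mid_c < seg_c$end[i])
      } else {
        ss <- seg_c[seg_c$state == state, , drop = FALSE]
        fp_bp <- sum(ss$end - ss$start)
        n <- 0
        for (i in seq_len(nrow(ss)))
          n <- n + sum(mid_c >= ss$start[i] & mid_c < ss$end[i])
      }
      if (fp_bp > 0)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, state = state, footprint_mb = fp_bp / 1e6,
          n_islands = n, density = n / (fp_bp / 1e6),
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when `min(n, m) <= 8`, `n + m <= 25` and there are no
#' ties; otherwise the normal approximation with tie correction. All samples
#' tied across both groups give p = 1.
#'
#' @param values_a,values_b non-empty numeric samples.
#' @return list with `U` (statistic for sample A) and `p_value`.
#' @export
mann_whitney <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  if (length(unique(c(values_a, values_b))) == 1)
    return(list(U = length(values_a) * length(values_b) / 2, p_value = 1))
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  use_exact <- !ties && min(length(values_a), length(values_b)) <= 8 &&
    length(values_a) + length(values_b) <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = use_exact,
                       correct = !use_exact))
  list(U = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Mapping-bias report: island density by state with Mann-Whitney tests
#'
#' Compares per-chromosome island densities in gain vs neutral and CNLOH vs
#' neutral footprints.
#'
#' @inheritParams density_by_state
#' @return list with `densities` (the [density_by_state()] table) and
#'   `tests` (data.frame comparison/U/p_value).
#' @export
cna_bias_report <- function(islands, segments, chrom_lengths) {
  dens <- density_by_state(islands, segments, chrom_lengths)
  get <- function(state) dens$density[dens$state == state]
  tests <- lapply(c(gain = "gain", CNLOH = "CNLOH"), function(state) {
    a <- get(state); b <- get("neutral")
    if (length(a) == 0 || length(b) == 0)
      return(data.frame(comparison = paste0(state, "_vs_neutral"),
                        U = NA_real_, p_value = NA_real_))
    mw <- mann_whitney(a, b)
    data.frame(comparison = paste0(state, "_vs_neutral"),
               U = mw$U, p_value = mw$p_value)
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(densities = dens, tests = tests)
}
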