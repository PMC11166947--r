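#' Pairwise mismatch rate between two pseudohaploid genomes
#'
#' Counts, over SNPs where both individuals carry a call, the fraction at
#' which the two sampled alleles differ. On pseudohaploid data the
#' expected rate is the unrelated-pair baseline scaled down by shared
#' ancestry, so relatedness degrees separate after normalization. Diploid
#' input is pseudohaploidized first (logged).
#'
#' @param geno a [geno_matrix()].
#' @param id1,id2 row names or indices of the pair.
#' @param min_overlap minimum overlapping SNPs for a usable estimate.
#' @param blocks optional [make_blocks()] partition; when supplied, a
#'   block-jackknife standard error of the rate is attached.
#' @param seed seed used only if a diploid individual must be
#'   pseudohaploidized.
#' @return A `pmr_result`: `pair`, `overlap`, `mismatch_rate`, `se`
#'   (or `NA`), `usable`; `normalized_score` and `degree` are filled by
#'   [classify_degrees()].
#' @export
pmr <- function(geno, id1, id2, min_overlap = 5000, blocks = NULL,
                seed = 1) {
  ids <- c(id1, id2)
  rows <- if (is.character(ids)) match(ids, rownames(geno$values)) else ids
  if (anyNA(rows)) stop("unknown individual id(s): ",
                        paste(ids[is.na(rows)], collapse = ", "))
  need_ph <- geno$ploidy[rows] != "pseudohaploid"
  v <- geno$values[rows, , drop = FALSE]
  if (any(need_ph)) {
    message("pseudohaploidizing diploid individual(s): ",
            paste(ids[need_ph], collapse = ", "))
    sub <- geno_matrix(v, "diploid")
    v <- degrade_to_pseudohaploid(sub, 0, seed = seed)$values
  }
  both <- !is.na(v[1, ]) & !is.na(v[2, ])
  overlap <- sum(both)
  mism <- v[1, both] != v[2, both]
  rate <- if (overlap > 0) mean(mism) else NA_real_
  se <- NA_real_
  if (!is.null(blocks) && overlap > 0) {
    bidx <- block_index(blocks, ncol(v))[both]
    bsum <- as.numeric(rowsum(as.numeric(mism), bidx))
    bcnt <- as.numeric(rowsum(rep(1, overlap), bidx))
    if (length(bcnt) >= 2) {
      loo <- (sum(bsum) - bsum) / (sum(bcnt) - bcnt)
      se <- weighted_jackknife(rate, loo, bcnt)$se
    }
  }
  structure(list(pair = as.character(ids), overlap = overlap,
                 mismatch_rate = rate, se = se,
                 usable = overlap >= min_overlap,
                 normalized_score = NA_real_, degree = NA_character_),
            class = "pmr_result")
}

#' @export
print.pmr_result <- function(x, ...) {
  cat(sprintf("<pmr> %s-%s: rate %.4f over %d SNPs%s%s\n", x$pair[1],
              x$pair[2], x$mismatch_rate, x$overlap,
              if (!is.na(x$normalized_score))
                sprintf(", normalized %.3f -> %s", x$normalized_score,
                        x$degree) else "",
              if (x$usable) "" else " [below min_overlap]"))
  invisible(x)
}

#' Classify relatedness degrees from normalized mismatch rates
#'
#' Normalizes each pair's mismatch rate by an unrelated-pair baseline
#' (the median rate across pairs, on the assumption that most pairs are
#' unrelated, or an externally supplied value) and bins the normalized
#' score with the READ cutoffs: `< 0.625` identical/twin, `[0.625,
#' 0.8125)` first degree, `[0.8125, 0.90625)` second degree, `>= 0.90625`
#' unrelated (third degree and beyond is not separated from unrelated).
#'
#' @param pairs a list of `pmr_result` objects.
#' @param normalization `"median"` or a single numeric baseline rate.
#' @return The input list with `normalized_score` and `degree` filled for
#'   usable pairs; baseline in attribute `baseline`.
#' @export
classify_degrees <- function(pairs, normalization = "median") {
  usable <- vapply(pairs, `[[`, TRUE, "usable")
  if (!any(usable)) stop("no usable pairs (all below min_overlap)")
  rates <- vapply(pairs, `[[`, 0, "mismatch_rate")
  if (identical(normalization, "median")) {
    if (sum(usable) < 5)
      warning("median normalization over fewer than 5 pairs is fragile")
    baseline <- median(rates[usable])
  } else {
    baseline <- as.numeric(normalization)
  }
  if (!is.finite(baseline) || baseline <= 0)
    stop("normalization baseline must be a positive rate")
  scores <- rates / baseline
  if (all(abs(scores[usable] - 1) < 1e-12))
    warning("all normalized scores are 1: degenerate cohort, ",
            "classification is uninformative")
  bands <- c(identical = 0.625, first = 0.8125, second = 0.90625)
  for (i in seq_along(pairs)) {
    if (!usable[i]) next
    pairs[[i]]$normalized_score <- scores[i]
    pairs[[i]]$degree <-
      if (scores[i] < bands["identical"]) "identical"
      else if (scores[i] < bands["first"]) "1st"
      else if (scores[i] < bands["second"]) "2nd"
      else "3rd+/unrelated"
  }
  attr(pairs, "baseline") <- baseline
  pairs
}

#' All-pairs PMR table for a cohort
#'
#' @param geno a [geno_matrix()] (pseudohaploid or diploid).
#' @param min_overlap,blocks,seed passed to [pmr()].
#' @param normalization passed to [classify_degrees()].
#' @return A `data.frame`: id1, id2, overlap, mismatch_rate, se,
#'   normalized_score, degree.
#' @export
pmr_cohort <- function(geno, min_overlap = 5000, blocks = NULL,
                       normalization = "median", seed = 1) {
  ids <- rownames(geno$values) %||% as.character(seq_len(nrow(geno$values)))
  combs <- utils::combn(length(ids), 2)
  pairs <- lapply(seq_len(ncol(combs)), function(k)
    pmr(geno, combs[1, k], combs[2, k], min_overlap, blocks, seed))
  pairs <- classify_degrees(pairs, normalization)
  data.frame(id1 = ids[combs[1, ]], id2 = ids[combs[2, ]],
             overlap = vapply(pairs, `[[`, 0, "overlap"),
             mismatch_rate = vapply(pairs, `[[`, 0, "mismatch_rate"),
             se = vapply(pairs, `[[`, 0, "se"),
             normalized_score = vapply(pairs, `[[`, 0, "normalized_score"),
             degree = vapply(pairs, `[[`, "", "degree"))
}
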