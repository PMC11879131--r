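# SHAPE-MaP-style mutational profiling. Chemical probing (NAI) marks
# flexible nucleotides; the adduct is read out as mutations during reverse
# transcription. Three channels are sequenced per RNA: modified (NAI),
# untreated (DMSO) and a denatured control. Reactivity at a position is
#
#   raw[i] = (rate_mod[i] - rate_unt[i]) / rate_den[i]
#
# where rate = mutation events / effective depth. Positions failing the
# per-channel depth threshold (default 500 reads) are masked rather than
# reported.

#' Count per-position mutation events and effective depth from alignments
#'
#' Walks each alignment's CIGAR (and MD tag, or SEQ-vs-reference comparison
#' when MD is absent) and accumulates: a mismatch at its own reference
#' position; each insertion and deletion as one event at the reference
#' position immediately 5' of the event. Events on one read closer than
#' `merge_distance` are merged into a single event at the 5'-most position
#' (nearby mutations arise from one reverse-transcriptase encounter).
#' Effective depth counts reference positions aligned to a read base, so a
#' deleted base is not covered. Reads mapped to a different reference are
#' skipped and counted; reads with mapping quality below `min_mapq` are
#' excluded.
#'
#' @param records a `sam_records` table (one probing channel).
#' @param reference reference sequence (named character of length 1, or an
#'   unnamed string with `ref_name` supplied).
#' @param ref_name reference name records must match; defaults to the name of
#'   `reference`, else the first mapped record's reference.
#' @param min_mapq minimum mapping quality (default 10).
#' @param merge_distance merge events on one read within this many nt
#'   (default 2).
#' @return object of class `mutation_counts`: list with integer vectors
#'   `events` and `depth` (length = reference length) and attrition counts.
#' @export
count_mutation_rates <- function(records, reference, ref_name = NULL,
                                 min_mapq = 10, merge_distance = 2) {
  refseq <- norm_seq(reference[[1]])
  L <- nchar(refseq)
  ref_name <- ref_name %||% names(reference)[1]
  events <- integer(L)
  depth <- integer(L)
  n_other_ref <- 0L
  n_low_mapq <- 0L
  if (nrow(records)) {
    use <- records$mapped
    if (is.na(ref_name)) ref_name <- records$rname[use][1]
    other <- use & records$rname != ref_name
    n_other_ref <- sum(other)
    use <- use & !other
    low <- use & records$mapq < min_mapq
    n_low_mapq <- sum(low)
    use <- use & !low
    for (r in which(use)) {
      w <- walk_alignment(records$pos[r], records$cigar[r], records$md[r],
                          records$seq[r], refseq)
      depth[w$cover + 1L] <- depth[w$cover + 1L] + 1L
      ev <- sort(unique(c(w$mism, w$ins_anchor, w$del_anchor)))
      if (length(ev) > 1 && merge_distance > 0) {
        keep <- rep(TRUE, length(ev))
        last <- ev[1]
        for (k in 2:length(ev)) {
          if (ev[k] - last <= merge_distance) keep[k] <- FALSE else last <- ev[k]
        }
        ev <- ev[keep]
      }
      ev <- ev[ev >= 0L & ev < L]
      events[ev + 1L] <- events[ev + 1L] + 1L
    }
  }
  structure(list(events = events, depth = depth),
            n_skipped_other_ref = n_other_ref,
            n_excluded_low_mapq = n_low_mapq,
            class = "mutation_counts")
}

#' Compute a reactivity profile from the three probing channels
#'
#' @param mod,unt,den `mutation_counts` for the modified (NAI), untreated
#'   (DMSO) and denatured channels.
#' @param depth_threshold minimum effective depth required in every channel
#'   (default 500); positions below it are masked, as are positions with a
#'   zero denatured mutation rate.
#' @return object of class `reactivity_profile`: list with `raw` (NA where
#'   masked), `norm` (filled by [normalize_reactivity()]), logical `mask`
#'   (TRUE = position passes), per-channel depths, and `depth_threshold`.
#' @export
compute_reactivity <- function(mod, unt, den, depth_threshold = 500) {
  L <- length(mod$events)
  stopifnot(length(unt$events) == L, length(den$events) == L)
  rate <- function(mc) ifelse(mc$depth > 0, mc$events / mc$depth, NA_real_)
  r_mod <- rate(mod); r_unt <- rate(unt); r_den <- rate(den)
  mask <- mod$depth >= depth_threshold & unt$depth >= depth_threshold &
    den$depth >= depth_threshold & !is.na(r_den) & r_den > 0
  raw <- rep(NA_real_, L)
  raw[mask] <- (r_mod[mask] - r_unt[mask]) / r_den[mask]
  structure(list(raw = raw, norm = rep(NA_real_, L), mask = mask,
                 depth_mod = mod$depth, depth_unt = unt$depth,
                 depth_den = den$depth, depth_threshold = depth_threshold),
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("reactivity_profile: %d positions, %d unmasked (depth >= %d)\n",
              length(x$raw), sum(x$mask), x$depth_threshold))
  invisible(x)
}

#' Normalize a reactivity profile by the 2-8% rule
#'
#' The scale factor is the mean of raw reactivities falling between the 90th
#' and 98th percentile of unmasked positions (i.e. excluding the top 2% as
#' outliers and averaging the next 8%); normalized reactivity is raw / scale.
#' Negative raw values are retained.
#'
#' @param profile a `reactivity_profile` with at least 20 unmasked
#'   positions.
#' @return the profile with `norm` filled in and the scale recorded as
#'   attribute `scale`.
#' @export
normalize_reactivity <- function(profile) {
  x <- profile$raw[profile$mask]
  if (length(x) < 20) stop("normalization failed: fewer than 20 unmasked positions")
  q <- stats::quantile(x, c(0.90, 0.98), names = FALSE)
  sel <- x >= q[1] & x <= q[2]
  scale <- mean(x[sel])
  if (!is.finite(scale) || scale <= 0) stop("normalization failed: scale <= 0")
  profile$norm <- profile$raw / scale
  attr(profile, "scale") <- scale
  profile
}

#' Per-domain structural divergence between GII and PIE reactivities
#'
#' For each annotated intron domain, computes the Pearson correlation between
#' the native-form (GII) reactivities and the permuted-form (PIE)
#' reactivities at the same intron positions, mapped through the layout's
#' coordinate correspondence. Only positions unmasked in both profiles are
#' used; domains with fewer than `min_positions` usable positions yield a
#' null (NA) row.
#'
#' @param gii_profile `reactivity_profile` over the GII reference.
#' @param pie_profile `reactivity_profile` over the PIE precursor.
#' @param layout the `pie_layout` relating the two references.
#' @param intron the [intron_spec()] carrying the domain annotation.
#' @param min_positions minimum co-unmasked positions per domain (default 5).
#' @param use_norm correlate normalized instead of raw reactivities (default
#'   FALSE; Pearson r is identical whenever both profiles are normalized by a
#'   single positive scale).
#' @return data.frame with columns `intron`, `domain`, `pearson_r`,
#'   `n_positions`.
#' @export
domain_divergence <- function(gii_profile, pie_profile, layout, intron,
                              min_positions = 5, use_norm = FALSE) {
  field <- if (use_norm) "norm" else "raw"
  dom <- intron$domains
  rows <- lapply(seq_len(nrow(dom)), function(k) {
    gpos <- dom$start[k]:(dom$end[k] - 1L)
    ppos <- map_gii_to_pie(layout, gpos)
    ok <- !is.na(ppos)
    gpos <- gpos[ok]; ppos <- ppos[ok]
    ok <- gii_profile$mask[gpos + 1L] & pie_profile$mask[ppos + 1L]
    g <- gii_profile[[field]][gpos + 1L][ok]
    p <- pie_profile[[field]][ppos + 1L][ok]
    n <- length(g)
    r <- if (n >= min_positions && stats::sd(g) > 0 && stats::sd(p) > 0)
      stats::cor(g, p) else NA_real_
    data.frame(intron = intron$name, domain = dom$label[k],
               pearson_r = r, n_positions = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Association between structural divergence and circularization efficiency
#'
#' For each domain, ranks introns by structural divergence (1 - pearson_r)
#' and tests the Spearman rank correlation with circularization efficiency.
#' The p-value is the exact permutation probability of an absolute rank
#' correlation at least as large as observed when n <= 8 introns (all n!
#' rank permutations enumerated), and the asymptotic t approximation
#' otherwise.
#'
#' @param table divergence table from [domain_divergence()] over >= 4
#'   introns (rows bound together).
#' @param circ_eff named numeric vector, circularization efficiency (in %)
#'   per intron; every intron in `table` must be present.
#' @return data.frame with columns `domain`, `spearman_rho`, `p_value`, `n`.
#' @export
divergence_association <- function(table, circ_eff) {
  introns <- unique(table$intron)
  if (length(introns) < 4) stop("insufficient groups: need >= 4 introns")
  if (!all(introns %in% names(circ_eff)))
    stop("missing circularization efficiency for: ",
         paste(setdiff(introns, names(circ_eff)), collapse = ", "))
  domains <- unique(table$domain)
  rows <- lapply(domains, function(d) {
    sub <- table[table$domain == d & !is.na(table$pearson_r), , drop = FALSE]
    x <- 1 - sub$pearson_r
    y <- unname(circ_eff[sub$intron])
    n <- length(x)
    if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      if (n >= 4) warning("degenerate ranks for domain ", d)
      return(data.frame(domain = d, spearman_rho = NA_real_,
                        p_value = NA_real_, n = n, stringsAsFactors = FALSE))
    }
    rho <- stats::cor(x, y, method = "spearman")
    p <- spearman_perm_p(x, y, rho)
    data.frame(domain = d, spearman_rho = rho, p_value = p, n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# two-sided Spearman p: exact enumeration of all rank permutations for
# n <= 8, asymptotic t approximation above
spearman_perm_p <- function(x, y, rho) {
  n <- length(x)
  if (n <= 8) {
    rx <- rank(x)
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx[pm], rank(y)))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Write a reactivity profile to TSV
#'
#' @param profile a `reactivity_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_reactivity_tsv <- function(profile, path) {
  df <- data.frame(position = seq_along(profile$raw) - 1L,
                   raw = profile$raw, norm = profile$norm,
                   depth_mod = profile$depth_mod,
                   depth_unt = profile$depth_unt,
                   depth_den = profile$depth_den,
                   mask = profile$mask)
  write_tsv_provenance(df, path,
                       list(depth_threshold = profile$depth_threshold))
}
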