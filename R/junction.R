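# Circularization-junction characterization: flank-anchored extraction of
# randomized (N60) exon-replacement inserts, position frequency matrices and
# information content, per-position junction error profiling from
# alignments, and pileup-based variant-frequency calling with replicate
# intersection for mutant selection.

#' Extract fixed-length randomized inserts by flank anchoring
#'
#' For each read, finds the first exact occurrence of the 5' flank and the
#' next occurrence of the 3' flank after it, and retains the intervening
#' sequence iff it has exactly the expected length. Retained inserts are
#' deduplicated. Bookkeeping counts satisfy
#' retained + n_flank_fail + n_length_fail + n_duplicates = n_reads_scanned.
#'
#' @param reads character vector of read sequences.
#' @param flank5,flank3 the 8-nt anchor sequences flanking the insert.
#' @param expected_length required insert length (default 60).
#' @param max_flank_mismatch mismatches tolerated in each flank (default 0,
#'   exact matching).
#' @param scan_revcomp also scan the reverse complement of reads whose
#'   forward strand has no flank match (default FALSE; amplicon orientation
#'   is fixed by the primers).
#' @return object of class `insert_library`: `inserts` (unique sequences),
#'   `flank5`, `flank3`, `expected_length`, and the bookkeeping counts.
#' @export
extract_inserts <- function(reads, flank5, flank3, expected_length = 60,
                            max_flank_mismatch = 0, scan_revcomp = FALSE) {
  flank5 <- norm_seq(flank5); flank3 <- norm_seq(flank3)
  if (flank5 == flank3) stop("degenerate anchors: flank5 equals flank3")
  reads <- norm_seq(reads)
  n <- length(reads)
  find_insert <- function(read) {
    if (max_flank_mismatch == 0) {
      i5 <- regexpr(flank5, read, fixed = TRUE)[1]
      if (i5 < 0) return(NULL)
      rest_start <- i5 + nchar(flank5)
      i3 <- regexpr(flank3, substring(read, rest_start), fixed = TRUE)[1]
      if (i3 < 0) return(NULL)
      substring(read, rest_start, rest_start + i3 - 2L)
    } else {
      s <- Biostrings::BString(read)
      m5 <- Biostrings::matchPattern(flank5, s, max.mismatch = max_flank_mismatch)
      if (!length(m5)) return(NULL)
      from <- BiocGenerics::end(m5)[1] + 1L
      m3 <- Biostrings::matchPattern(flank3, s, max.mismatch = max_flank_mismatch)
      m3_ok <- BiocGenerics::start(m3) >= from
      if (!any(m3_ok)) return(NULL)
      to <- BiocGenerics::start(m3)[m3_ok][1] - 1L
      if (to < from) "" else as.character(Biostrings::subseq(s, from, to))
    }
  }
  found <- vapply(reads, function(read) {
    ins <- find_insert(read)
    if (is.null(ins) && scan_revcomp) ins <- find_insert(revcomp(read))
    if (is.null(ins)) NA_character_ else ins
  }, "", USE.NAMES = FALSE)
  n_flank_fail <- sum(is.na(found))
  candidates <- found[!is.na(found)]
  n_length_fail <- sum(nchar(candidates) != expected_length)
  candidates <- candidates[nchar(candidates) == expected_length]
  dup <- duplicated(candidates)
  n_duplicates <- sum(dup)
  retained <- candidates[!dup]
  structure(list(flank5 = flank5, flank3 = flank3,
                 expected_length = expected_length,
                 inserts = retained,
                 n_reads_scanned = n,
                 n_retained = length(retained),
                 n_flank_fail = n_flank_fail,
                 n_length_fail = n_length_fail,
                 n_duplicates = n_duplicates),
            class = "insert_library")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.insert_library <- function(x, ...) {
  cat(sprintf(paste0("insert_library: %d unique %d-nt inserts from %d reads ",
                     "(%d flank-fail, %d length-fail, %d duplicates)\n"),
              x$n_retained, x$expected_length, x$n_reads_scanned,
              x$n_flank_fail, x$n_length_fail, x$n_duplicates))
  invisible(x)
}

#' Build a position frequency matrix from equal-length sequences
#'
#' Computes per-position base counts (via Biostrings), frequencies,
#' information content IC(p) = 2 + sum_b f_b log2 f_b bits against a uniform
#' background, and a consensus string (the majority base where its frequency
#' reaches `consensus_threshold`, else N).
#'
#' @param inserts character vector (or an `insert_library`) of equal-length
#'   sequences; at least one.
#' @param consensus_threshold frequency required to call a consensus base
#'   (default 0.9).
#' @return object of class `pfm`: `counts` (4 x L), `frequencies`,
#'   `information_content` (bits), `consensus`.
#' @export
build_pfm <- function(inserts, consensus_threshold = 0.9) {
  if (inherits(inserts, "insert_library")) inserts <- inserts$inserts
  if (!length(inserts)) stop("no inserts")
  if (length(unique(nchar(inserts))) != 1) stop("unequal insert lengths")
  set <- Biostrings::DNAStringSet(inserts)
  counts <- Biostrings::consensusMatrix(set, baseOnly = TRUE)[c("A", "C", "G", "T"), ,
                                                             drop = FALSE]
  totals <- colSums(counts)
  freqs <- sweep(counts, 2, pmax(totals, 1), "/")
  ic <- apply(freqs, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  ic[totals == 0] <- NA_real_
  consensus <- vapply(seq_len(ncol(freqs)), function(j) {
    if (totals[j] == 0) return("N")
    b <- which.max(freqs[, j])
    if (freqs[b, j] >= consensus_threshold) rownames(freqs)[b] else "N"
  }, "")
  structure(list(counts = counts, frequencies = freqs,
                 information_content = unname(ic),
                 consensus = paste(consensus, collapse = "")),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm: %d positions, consensus %s\n",
              ncol(x$counts), x$consensus))
  invisible(x)
}

#' Per-position error rates around a ligated junction
#'
#' Given alignments against the linearized circular product (see
#' [predict_circle()]), computes at each position the fraction of covering
#' reads carrying an insertion (anchored at the reference position
#' immediately 5' of the inserted bases), a deletion (counted at each
#' deleted reference position; depth there includes the reads spanning the
#' deletion), or a mismatch. The three classes are mutually exclusive per
#' event; one read can contribute events at several positions.
#'
#' @param records `sam_records` aligned to the junction reference.
#' @param reference the junction reference sequence.
#' @param window optional 0-based half-open interval to restrict the
#'   profile; default whole reference.
#' @param ref_name,min_mapq as in [count_mutation_rates()].
#' @return data.frame of class `junction_error_profile`: `position`,
#'   `depth`, `insertion_rate`, `deletion_rate`, `mismatch_rate` (NA where
#'   depth is 0).
#' @export
junction_error_profile <- function(records, reference, window = NULL,
                                   ref_name = NULL, min_mapq = 0) {
  refseq <- norm_seq(reference[[1]])
  L <- nchar(refseq)
  window <- if (is.null(window)) c(0L, L) else check_interval(window, L, "window")
  ref_name <- ref_name %||% names(reference)[1]
  depth <- integer(L); ins <- integer(L); del <- integer(L); mism <- integer(L)
  if (nrow(records)) {
    use <- records$mapped & records$mapq >= min_mapq
    if (!is.na(ref_name)) use <- use & records$rname == ref_name
    for (r in which(use)) {
      w <- walk_alignment(records$pos[r], records$cigar[r], records$md[r],
                          records$seq[r], refseq)
      span <- sort(unique(c(w$cover, w$del_span)))
      depth[span + 1L] <- depth[span + 1L] + 1L
      if (length(w$mism)) mism[w$mism + 1L] <- mism[w$mism + 1L] + 1L
      if (length(w$ins_anchor)) ins[w$ins_anchor + 1L] <- ins[w$ins_anchor + 1L] + 1L
      if (length(w$del_span)) del[w$del_span + 1L] <- del[w$del_span + 1L] + 1L
    }
  }
  idx <- (window[1] + 1L):window[2]
  if (all(depth[idx] == 0)) stop("zero depth across the requested window")
  rate <- function(ev) ifelse(depth[idx] > 0, ev[idx] / depth[idx], NA_real_)
  out <- data.frame(position = idx - 1L, depth = depth[idx],
                    insertion_rate = rate(ins),
                    deletion_rate = rate(del),
                    mismatch_rate = rate(mism))
  class(out) <- c("junction_error_profile", "data.frame")
  out
}

#' Summarize maximal junction error rates by region
#'
#' @param profile a `junction_error_profile`.
#' @param regions per-position labels (same reference frame as the
#'   profile).
#' @return data.frame with the maximum insertion/deletion/mismatch rate per
#'   region group.
#' @export
junction_error_summary <- function(profile, regions) {
  lab <- regions[profile$position + 1L]
  groups <- split(seq_len(nrow(profile)), lab)
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(region = g,
               max_insertion_rate = max(profile$insertion_rate[i], na.rm = TRUE),
               max_deletion_rate = max(profile$deletion_rate[i], na.rm = TRUE),
               max_mismatch_rate = max(profile$mismatch_rate[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call variant frequencies from a pileup
#'
#' For every position and non-reference base whose frequency reaches
#' `min_var_freq`, reports the variant frequency and a one-sided exact
#' binomial enrichment p-value P(X >= alt_count | n = depth, p =
#' error_rate) against the sequencing error rate.
#'
#' @param pileup data.frame with columns `position` (0-based) and base
#'   counts `A`, `C`, `G`, `T` (extra columns ignored).
#' @param ref reference sequence.
#' @param min_var_freq minimum variant frequency to report (default 0.001).
#' @param error_rate assumed per-base error rate for the null (default
#'   0.001).
#' @return data.frame of variant calls sorted by position: `position`,
#'   `ref`, `alt`, `alt_count`, `depth`, `var_freq`, `p_value`.
#' @export
call_variant_frequencies <- function(pileup, ref, min_var_freq = 0.001,
                                     error_rate = 0.001) {
  refseq <- norm_seq(ref[[1]])
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (k in seq_len(nrow(pileup))) {
    pos <- pileup$position[k]
    counts <- as.numeric(pileup[k, bases])
    depth <- sum(counts)
    if (depth == 0) next
    refb <- substr(refseq, pos + 1L, pos + 1L)
    for (b in bases[bases != refb]) {
      alt <- counts[match(b, bases)]
      if (alt == 0) next
      vf <- alt / depth
      if (vf < min_var_freq) next
      p <- stats::pbinom(alt - 1, depth, error_rate, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(position = pos, ref = refb, alt = b,
                   alt_count = alt, depth = depth, var_freq = vf,
                   p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(position = integer(0), ref = character(0),
                  alt = character(0), alt_count = numeric(0),
                  depth = numeric(0), var_freq = numeric(0),
                  p_value = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect enriched variants across replicate samples
#'
#' Keeps the variants (position, alt) called with enrichment p-value below
#' `alpha` in every sample, and reports the mean variant frequency across
#' samples, sorted descending — the selection rule for enriched IRES
#' mutants.
#'
#' @param samples non-empty list of variant-call tables from
#'   [call_variant_frequencies()].
#' @param alpha selection significance level (default 0.05).
#' @return data.frame: `position`, `alt`, `mean_var_freq`, `n_samples`.
#' @export
intersect_enriched_variants <- function(samples, alpha = 0.05) {
  if (!length(samples)) stop("empty sample list")
  keysets <- lapply(samples, function(s) {
    s <- s[!is.na(s$p_value) & s$p_value < alpha, , drop = FALSE]
    setNames(s$var_freq, paste(s$position, s$alt))
  })
  common <- Reduce(intersect, lapply(keysets, names))
  if (!length(common))
    return(data.frame(position = integer(0), alt = character(0),
                      mean_var_freq = numeric(0), n_samples = integer(0),
                      stringsAsFactors = FALSE))
  mean_vf <- vapply(common, function(k) {
    mean(vapply(keysets, function(v) unname(v[k]), 0))
  }, 0)
  parts <- strsplit(common, " ", fixed = TRUE)
  out <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                    alt = vapply(parts, `[`, "", 2),
                    mean_var_freq = unname(mean_vf),
                    n_samples = length(samples),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_var_freq, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
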