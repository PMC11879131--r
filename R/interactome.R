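# SPLASH proximity-ligation interactome analysis. Psoralen cross-linking and
# proximity ligation turn base-paired RNA regions into chimeric sequencing
# reads: a primary alignment plus an SA-tagged supplementary alignment on the
# same reference. The pipeline is dedup -> chimera extraction -> filtering ->
# binning into 10-nt windows -> normalization by total mapped reads, with
# region classification and replicate-level differential testing on top.

#' Collapse PCR duplicates among SAM records
#'
#' Records sharing (reference, leftmost position, strand, CIGAR) are
#' considered PCR duplicates and collapsed to one representative (the first).
#' Deduplication is decided on primary alignments; secondary/supplementary
#' lines follow their primary's fate (a read whose primary is dropped loses
#' its supplementary lines too).
#'
#' @param records a `sam_records` table.
#' @return deduplicated `sam_records`, with attribute `n_removed`.
#' @export
dedupe_reads <- function(records) {
  if (!nrow(records)) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  prim <- which(records$primary & records$mapped)
  key <- paste(records$rname[prim], records$pos[prim], records$strand[prim],
               records$cigar[prim], sep = "\1")
  keep_prim <- prim[!duplicated(key)]
  kept_qnames <- records$qname[keep_prim]
  is_dropped_prim <- records$primary & records$mapped &
    !(seq_len(nrow(records)) %in% keep_prim)
  keep <- !is_dropped_prim &
    (records$primary | records$qname %in% kept_qnames)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(records) - nrow(out)
  out
}

#' Extract two-arm chimeras from deduplicated alignments
#'
#' A chimeric read is a mapped, plus-strand primary alignment carrying
#' exactly one SA entry on the same reference and strand. Arm intervals are
#' the aligned reference spans of the primary and supplementary alignments,
#' ordered so `arm1` starts first; the chimera's mapping quality is the
#' minimum of the two arms' (SA entries without a mapping quality pass).
#' Primaries with more than one SA entry (3-arm chimeras) are discarded and
#' counted. `total_mapped` counts every mapped primary alignment, chimeric or
#' not, on either strand.
#'
#' @param records deduplicated `sam_records`.
#' @return list of class `chimera_set`: `chimeras` data.frame (`read_id`,
#'   `arm1_start`, `arm1_end`, `arm2_start`, `arm2_end`, `mapq`),
#'   `total_mapped`, and counts `n_multi_sa`, `n_malformed_sa`,
#'   `n_minus_strand`.
#' @export
extract_chimeras <- function(records) {
  prim <- records[records$primary & records$mapped, , drop = FALSE]
  total_mapped <- nrow(prim)
  n_multi <- 0L; n_malformed <- 0L; n_minus <- 0L
  rows <- vector("list", nrow(prim))
  for (k in seq_len(nrow(prim))) {
    sa <- prim$sa[k]
    if (is.na(sa) || !nzchar(sa)) next
    if (prim$strand[k] == "-") { n_minus <- n_minus + 1L; next }
    ent <- tryCatch(parse_sa_tag(sa), error = function(e) NULL)
    if (is.null(ent)) { n_malformed <- n_malformed + 1L; next }
    if (nrow(ent) > 1) { n_multi <- n_multi + 1L; next }
    if (nrow(ent) < 1) next
    if (ent$rname != prim$rname[k] || ent$strand != prim$strand[k]) next
    a1 <- c(prim$pos[k], prim$pos[k] + cigar_ref_span(prim$cigar[k]))
    a2 <- c(ent$pos, ent$pos + cigar_ref_span(ent$cigar))
    if (a2[1] < a1[1]) { tmp <- a1; a1 <- a2; a2 <- tmp }
    mq <- if (is.na(ent$mapq)) prim$mapq[k] else min(prim$mapq[k], ent$mapq)
    rows[[k]] <- data.frame(read_id = prim$qname[k],
                            arm1_start = a1[1], arm1_end = a1[2],
                            arm2_start = a2[1], arm2_end = a2[2],
                            mapq = mq, stringsAsFactors = FALSE)
  }
  chim <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(chim))
    chim <- data.frame(read_id = character(0), arm1_start = integer(0),
                       arm1_end = integer(0), arm2_start = integer(0),
                       arm2_end = integer(0), mapq = integer(0),
                       stringsAsFactors = FALSE)
  structure(list(chimeras = chim, total_mapped = total_mapped,
                 n_multi_sa = n_multi, n_malformed_sa = n_malformed,
                 n_minus_strand = n_minus),
            class = "chimera_set")
}

#' Filter chimeras on mapping quality, arm span and junction consistency
#'
#' Keeps chimeras with mapping quality strictly greater than `min_mapq` and
#' arm span strictly greater than `min_arm_span` (by default each arm's
#' aligned reference length; `span_mode = "gap"` instead requires the
#' inter-arm gap to exceed the threshold). Chimeras whose arm pair is
#' consistent with the ligated E1-E2 junction — one arm ending within
#' `junction_tolerance` of E1's 3' end while the other starts within
#' tolerance of E2's 5' start — are removed, because such reads report the
#' circular conformation of the product rather than a structural contact in
#' the precursor.
#'
#' @param chimera_set a `chimera_set` (or bare chimera data.frame).
#' @param layout the `pie_layout` providing the exon intervals.
#' @param min_mapq exclusive mapping-quality threshold (default 20).
#' @param min_arm_span exclusive arm-span threshold in nt (default 10).
#' @param junction_tolerance nt tolerance for junction-read matching
#'   (default 5).
#' @param span_mode `"arm_length"` (default) or `"gap"`.
#' @return filtered `chimera_set` (counts of removals as attributes), or a
#'   filtered data.frame when a data.frame was given.
#' @export
filter_chimeras <- function(chimera_set, layout, min_mapq = 20,
                            min_arm_span = 10, junction_tolerance = 5,
                            span_mode = c("arm_length", "gap")) {
  span_mode <- match.arg(span_mode)
  chim <- if (inherits(chimera_set, "chimera_set")) chimera_set$chimeras
          else chimera_set
  if (nrow(chim)) {
    ok_mapq <- chim$mapq > min_mapq
    ok_span <- if (span_mode == "arm_length") {
      (chim$arm1_end - chim$arm1_start) > min_arm_span &
        (chim$arm2_end - chim$arm2_start) > min_arm_span
    } else {
      (chim$arm2_start - chim$arm1_end) > min_arm_span
    }
    e1_end <- layout$e1_interval[2]
    e2_start <- layout$e2_interval[1]
    near <- function(a, b) abs(a - b) <= junction_tolerance
    junction <- (near(chim$arm1_end, e1_end) & near(chim$arm2_start, e2_start)) |
      (near(chim$arm1_start, e2_start) & near(chim$arm2_end, e1_end))
    keep <- ok_mapq & ok_span & !junction
    out <- chim[keep, , drop = FALSE]
    rownames(out) <- NULL
    n_mapq <- sum(!ok_mapq); n_span <- sum(ok_mapq & !ok_span)
    n_junc <- sum(ok_mapq & ok_span & junction)
  } else {
    out <- chim; n_mapq <- n_span <- n_junc <- 0L
  }
  if (inherits(chimera_set, "chimera_set")) {
    chimera_set$chimeras <- out
    attr(chimera_set, "n_removed_mapq") <- n_mapq
    attr(chimera_set, "n_removed_span") <- n_span
    attr(chimera_set, "n_removed_junction") <- n_junc
    chimera_set
  } else out
}

#' Bin chimeras into window-pair counts and normalize
#'
#' Each arm is assigned to the window containing its 5'-most coordinate
#' (window index = floor(start / window_size)); the key is the ordered window
#' pair. Window pairs supported by a single chimeric read are dropped as
#' background noise; counts are normalized by the total mapped reads of the
#' construct.
#'
#' @param chimera_set a `chimera_set`, or a chimera data.frame with
#'   `total_mapped` supplied.
#' @param window_size window width in nt (default 10).
#' @param total_mapped total mapped primary reads; taken from the
#'   `chimera_set` when omitted. Must be > 0.
#' @return object of class `interaction_map`: `window_size`, `counts`
#'   data.frame (`win_i`, `win_j`, `count`, `normalized`), `total_mapped`.
#' @export
bin_and_normalize <- function(chimera_set, window_size = 10,
                              total_mapped = NULL) {
  chim <- if (inherits(chimera_set, "chimera_set")) chimera_set$chimeras
          else chimera_set
  total_mapped <- total_mapped %||%
    (if (inherits(chimera_set, "chimera_set")) chimera_set$total_mapped else NULL)
  if (is.null(total_mapped) || total_mapped == 0)
    stop("total_mapped must be > 0")
  if (nrow(chim)) {
    wi <- pmin(chim$arm1_start, chim$arm2_start) %/% window_size
    wj <- pmax(chim$arm1_start, chim$arm2_start) %/% window_size
    key <- paste(pmin(wi, wj), pmax(wi, wj))
    tab <- table(key)
    tab <- tab[tab >= 2]
    if (length(tab)) {
      ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
      counts <- data.frame(win_i = as.integer(ij[, 1]),
                           win_j = as.integer(ij[, 2]),
                           count = as.integer(tab))
      counts <- counts[order(counts$win_i, counts$win_j), , drop = FALSE]
      rownames(counts) <- NULL
      counts$normalized <- counts$count / total_mapped
    } else counts <- empty_counts()
  } else counts <- empty_counts()
  structure(list(window_size = window_size, counts = counts,
                 total_mapped = total_mapped),
            class = "interaction_map")
}

empty_counts <- function() {
  data.frame(win_i = integer(0), win_j = integer(0), count = integer(0),
             normalized = numeric(0))
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("interaction_map: %d window pairs (window %d nt, %d mapped reads)\n",
              nrow(x$counts), x$window_size, x$total_mapped))
  invisible(x)
}

INTERACTION_CATEGORIES <- c("homology-involved",
                            "intron-intron same-domain",
                            "intron-intron cross-domain",
                            "intron-GOI", "GOI-GOI", "other")

window_labels <- function(regions, window_size, n_windows) {
  vapply(seq_len(n_windows) - 1L, function(w) {
    lo <- w * window_size + 1L
    hi <- min((w + 1L) * window_size, length(regions))
    if (lo > length(regions)) return("other")
    tab <- table(regions[lo:hi])
    names(tab)[which.max(tab)]
  }, "")
}

is_intron_label <- function(lab) {
  !(lab %in% c("H1", "H2", "IRES", "GOI", "E1", "E2"))
}

classify_pair <- function(l1, l2) {
  if (l1 %in% c("H1", "H2") || l2 %in% c("H1", "H2")) return("homology-involved")
  i1 <- is_intron_label(l1); i2 <- is_intron_label(l2)
  if (i1 && i2) {
    if (l1 == l2) return("intron-intron same-domain")
    return("intron-intron cross-domain")
  }
  if ((i1 && l2 == "GOI") || (i2 && l1 == "GOI")) return("intron-GOI")
  if (l1 == "GOI" && l2 == "GOI") return("GOI-GOI")
  "other"
}

#' Classify window-pair interactions by region
#'
#' Each window takes the majority region label of its positions; each window
#' pair is then assigned one category, with precedence: homology-involved,
#' then intron-intron same-domain / cross-domain, intron-GOI, GOI-GOI,
#' other. The categories partition the window pairs, so the per-category
#' aggregates sum to the map's total normalized signal.
#'
#' @param map an `interaction_map`.
#' @param regions per-position region labels from [annotate_regions()].
#' @return list of class `interaction_classes`: `pairs` (the count table
#'   with a `category` column) and `aggregates` (per-category summed
#'   normalized counts over all six categories).
#' @export
classify_interactions <- function(map, regions) {
  n_windows <- ceiling(length(regions) / map$window_size)
  wl <- window_labels(regions, map$window_size, n_windows)
  pairs <- map$counts
  pairs$category <- vapply(seq_len(nrow(pairs)), function(k) {
    l1 <- if (pairs$win_i[k] < n_windows) wl[pairs$win_i[k] + 1L] else "other"
    l2 <- if (pairs$win_j[k] < n_windows) wl[pairs$win_j[k] + 1L] else "other"
    classify_pair(l1, l2)
  }, "")
  agg <- vapply(INTERACTION_CATEGORIES, function(cat) {
    sum(pairs$normalized[pairs$category == cat])
  }, 0)
  structure(list(pairs = pairs,
                 aggregates = data.frame(category = INTERACTION_CATEGORIES,
                                         normalized = unname(agg),
                                         stringsAsFactors = FALSE)),
            class = "interaction_classes")
}

#' Differential interaction testing between two groups of replicates
#'
#' For every key (window pair, or region category when `level =
#' "category"`), performs an independent two-sample pooled-variance
#' (equal-variance) t-test on the normalized counts across replicates; keys
#' absent from a replicate are observed zeros. Raw p-values are reported
#' with a significance flag at p < .05 and no multiplicity correction. When
#' both groups are constant and equal the key is reported with t = 0,
#' p = 1.
#'
#' @param groupA,groupB lists of `interaction_map` replicates (>= 2 each).
#' @param level `"window-pair"` or `"category"`.
#' @param regions per-position region labels, required for `level =
#'   "category"`.
#' @return data.frame with key columns (`win_i`/`win_j` or `category`),
#'   `t`, `p`, `meanA`, `meanB`, `significant`.
#' @export
differential_interactions <- function(groupA, groupB,
                                      level = c("window-pair", "category"),
                                      regions = NULL) {
  level <- match.arg(level)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need >= 2 replicates per group")
  values_of <- function(m) {
    if (level == "window-pair") {
      setNames(m$counts$normalized, paste(m$counts$win_i, m$counts$win_j))
    } else {
      if (is.null(regions)) stop("regions required for category-level testing")
      cl <- classify_interactions(m, regions)
      setNames(cl$aggregates$normalized, cl$aggregates$category)
    }
  }
  va <- lapply(groupA, values_of)
  vb <- lapply(groupB, values_of)
  keys <- sort(unique(c(unlist(lapply(va, names)), unlist(lapply(vb, names)))))
  pull <- function(v, k) if (k %in% names(v)) unname(v[k]) else 0
  rows <- lapply(keys, function(k) {
    a <- vapply(va, pull, 0, k)
    b <- vapply(vb, pull, 0, k)
    tt <- pooled_t(a, b)
    if (level == "window-pair") {
      ij <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
      data.frame(win_i = ij[1], win_j = ij[2], t = tt$t, p = tt$p,
                 meanA = mean(a), meanB = mean(b),
                 significant = !is.na(tt$p) && tt$p < 0.05)
    } else {
      data.frame(category = k, t = tt$t, p = tt$p,
                 meanA = mean(a), meanB = mean(b),
                 significant = !is.na(tt$p) && tt$p < 0.05,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# closed-form pooled-variance two-sample t; degenerate zero-variance groups
# are handled explicitly (equal means -> t = 0, p = 1)
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff == 0) return(list(t = 0, p = 1))
    return(list(t = sign(diff) * Inf, p = 0))
  }
  t_stat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Export arc-plot coordinates for an interaction map
#'
#' One row per window pair with the window midpoints in nt, ready for arc
#' plotting.
#'
#' @param map an `interaction_map`.
#' @return data.frame with `x1`, `x2` (window centers), `count`,
#'   `normalized`.
#' @export
arc_coordinates <- function(map) {
  w <- map$window_size
  data.frame(x1 = map$counts$win_i * w + w / 2,
             x2 = map$counts$win_j * w + w / 2,
             count = map$counts$count,
             normalized = map$counts$normalized)
}
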