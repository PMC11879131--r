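# Group I intron and permuted intron-exon (PIE) construct modelling.
#
# A group I intron (GII) in its native context is E1 - intron - E2. The PIE
# rearrangement splits the intron inside its P6 helix and rebuilds the
# precursor as
#
#   H1 | 3'intron+E2 | IRES | GOI | E1+5'intron | H2
#
# so that self-splicing excises the two intron halves and ligates E1 to E2,
# yielding a circular RNA E2-IRES-GOI-E1. `gii_map` keeps the coordinate
# correspondence between precursor and native-intron positions so that
# probing signals measured on the two forms can be compared base by base.

#' Describe a group I intron and its domain annotation
#'
#' @param name identifier.
#' @param sequence the GII-form sequence (optionally with E1/E2 exon
#'   context). RNA alphabet is normalized to DNA.
#' @param domains data.frame with columns `label` (P1..P9, L2, L9, ...),
#'   `start`, `end` in 0-based half-open GII coordinates.
#' @param split_point GII coordinate inside the P6 interval where the
#'   permutation cuts; defaults to the midpoint of the annotated P6 interval.
#' @return object of class `intron_spec`.
#' @export
intron_spec <- function(name, sequence, domains, split_point = NULL) {
  sequence <- norm_seq(sequence)
  len <- nchar(sequence)
  stopifnot(is.data.frame(domains),
            all(c("label", "start", "end") %in% names(domains)))
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  if (any(domains$start < 0L) || any(domains$end > len) ||
      any(domains$start >= domains$end))
    stop("domain intervals must lie within [0, sequence length)")
  pdom <- domains[grepl("^P[1-9]$", domains$label), , drop = FALSE]
  if (nrow(pdom) > 1) {
    o <- order(pdom$start)
    if (any(pdom$start[o][-1] < pdom$end[o][-nrow(pdom)]))
      stop("P-domain intervals must not overlap")
  }
  p6 <- domains[domains$label == "P6", , drop = FALSE]
  if (is.null(split_point)) {
    if (!nrow(p6)) stop("no P6 domain annotated and no split_point given")
    split_point <- (p6$start[1] + p6$end[1]) %/% 2L
  }
  split_point <- as.integer(split_point)
  if (!nrow(p6) || split_point < p6$start[1] || split_point >= p6$end[1])
    stop("invalid split: split_point must lie within the P6 interval")
  structure(list(name = name, sequence = sequence, domains = domains,
                 split_point = split_point),
            class = "intron_spec")
}

#' @export
print.intron_spec <- function(x, ...) {
  cat(sprintf("intron_spec '%s': %d nt, %d domains, split_point %d\n",
              x$name, nchar(x$sequence), nrow(x$domains), x$split_point))
  invisible(x)
}

#' Build a PIE precursor layout from a group I intron
#'
#' Splits the intron at `split_point` and assembles the precursor
#' H1, (3'intron + E2), IRES, GOI, (E1 + 5'intron), H2. The exon intervals
#' `e1` and `e2` are given in GII coordinates and must abut the intron: E1
#' ends at the 5' splice site and E2 begins at the 3' splice site; the
#' intron proper is the interval between them.
#'
#' @param intron an [intron_spec()].
#' @param e1,e2 0-based half-open GII intervals of exon 1 and exon 2.
#' @param ires,goi,h1,h2 sequences for the internal ribosome entry site, the
#'   gene of interest, and the 5'/3' homology arms (any may be empty).
#' @return object of class `pie_layout` with the segment table, exon
#'   intervals in precursor coordinates, the precursor sequence, and
#'   `gii_map` (precursor position -> GII position, NA outside intron/exon
#'   segments).
#' @export
build_pie <- function(intron, e1, e2, ires = "", goi = "", h1 = "", h2 = "") {
  stopifnot(inherits(intron, "intron_spec"))
  len <- nchar(intron$sequence)
  e1 <- check_interval(e1, len, "e1")
  e2 <- check_interval(e2, len, "e2")
  if (e1[2] > e2[1]) stop("e1 must precede e2")
  istart <- e1[2] # 5' splice site: intron begins where E1 ends
  iend <- e2[1]   # 3' splice site: intron ends where E2 begins
  if (iend <= istart) stop("e1/e2 overlap the intron interval")
  split <- intron$split_point
  if (split <= istart || split >= iend)
    stop("invalid split: split_point not inside the intron interval")
  ires <- norm_seq(ires); goi <- norm_seq(goi)
  h1 <- norm_seq(h1); h2 <- norm_seq(h2)

  s <- intron$sequence
  i3 <- substr0(s, split, iend)      # 3' intron half
  i5 <- substr0(s, istart, split)    # 5' intron half
  e1s <- substr0(s, e1[1], e1[2])
  e2s <- substr0(s, e2[1], e2[2])

  parts <- c(H1 = h1, I3E2 = paste0(i3, e2s), IRES = ires, GOI = goi,
             E1I5 = paste0(e1s, i5), H2 = h2)
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens
  segments <- data.frame(role = names(parts), start = as.integer(starts),
                         end = as.integer(ends), stringsAsFactors = FALSE)
  precursor <- paste(parts, collapse = "")
  plen <- nchar(precursor)

  gii_map <- rep(NA_integer_, plen)
  i3e2_start <- segments$start[segments$role == "I3E2"]
  e1i5_start <- segments$start[segments$role == "E1I5"]
  n_i3 <- nchar(i3); n_e2 <- nchar(e2s); n_e1 <- nchar(e1s); n_i5 <- nchar(i5)
  if (n_i3) gii_map[i3e2_start + 1:n_i3] <- split + 0:(n_i3 - 1L)
  if (n_e2) gii_map[i3e2_start + n_i3 + 1:n_e2] <- e2[1] + 0:(n_e2 - 1L)
  if (n_e1) gii_map[e1i5_start + 1:n_e1] <- e1[1] + 0:(n_e1 - 1L)
  if (n_i5) gii_map[e1i5_start + n_e1 + 1:n_i5] <- istart + 0:(n_i5 - 1L)

  structure(list(
    segments = segments,
    e1_interval = c(e1i5_start, e1i5_start + n_e1),
    e2_interval = c(i3e2_start + n_i3, i3e2_start + n_i3 + n_e2),
    precursor_sequence = precursor,
    gii_map = gii_map,
    intron_name = intron$name,
    gii_e1 = e1, gii_e2 = e2,
    gii_intron = c(istart, iend)
  ), class = "pie_layout")
}

#' @export
print.pie_layout <- function(x, ...) {
  cat(sprintf("pie_layout '%s': precursor %d nt\n", x$intron_name,
              nchar(x$precursor_sequence)))
  print(x$segments)
  invisible(x)
}

#' Map precursor positions to native-intron (GII) coordinates
#'
#' @param layout a `pie_layout`.
#' @param pos vector of 0-based precursor positions.
#' @return integer vector of GII positions; NA for positions in H1/H2, IRES
#'   or GOI segments.
#' @export
map_pie_to_gii <- function(layout, pos) {
  plen <- nchar(layout$precursor_sequence)
  if (any(pos < 0L | pos >= plen)) stop("position out of range")
  layout$gii_map[pos + 1L]
}

#' Map GII coordinates back to precursor positions
#'
#' Inverse of [map_pie_to_gii()] over the intron/exon positions.
#'
#' @param layout a `pie_layout`.
#' @param gii_pos vector of 0-based GII positions.
#' @return integer vector of precursor positions; NA where the GII position
#'   is not part of the construct (outside intron and exons).
#' @export
map_gii_to_pie <- function(layout, gii_pos) {
  inv <- rep(NA_integer_, max(layout$gii_map, na.rm = TRUE) + 1L)
  mapped <- which(!is.na(layout$gii_map))
  inv[layout$gii_map[mapped] + 1L] <- mapped - 1L
  out <- rep(NA_integer_, length(gii_pos))
  ok <- gii_pos >= 0L & gii_pos < length(inv)
  out[ok] <- inv[gii_pos[ok] + 1L]
  out
}

#' Predict the circular splicing product of a PIE precursor
#'
#' Self-splicing excises both intron halves and ligates E1 to E2; the
#' resulting circle is reported linearized starting at the first base of E2,
#' so the E1->E2 ligation junction sits between the last and first base of
#' the linearization.
#'
#' @param layout a `pie_layout`.
#' @return object of class `circular_product` with fields `sequence` and
#'   `junction_index` (0-based position of the last E1 base).
#' @export
predict_circle <- function(layout) {
  p <- layout$precursor_sequence
  seg <- layout$segments
  seg_seq <- function(role) {
    r <- seg[seg$role == role, ]
    substr0(p, r$start, r$end)
  }
  e2s <- substr0(p, layout$e2_interval[1], layout$e2_interval[2])
  e1s <- substr0(p, layout$e1_interval[1], layout$e1_interval[2])
  circle <- paste0(e2s, seg_seq("IRES"), seg_seq("GOI"), e1s)
  structure(list(sequence = circle, junction_index = nchar(circle) - 1L),
            class = "circular_product")
}

#' @export
print.circular_product <- function(x, ...) {
  cat(sprintf("circular_product: %d nt, junction at %d|0\n",
              nchar(x$sequence), x$junction_index))
  invisible(x)
}

#' Sequence context across the E1-E2 ligation junction
#'
#' Returns the last `k` bases of E1 followed by the first `k` bases of E2 —
#' the flank pair used to anchor junction-read extraction.
#'
#' @param circle a `circular_product`.
#' @param k flank length on each side (default 8).
#' @return character 2k-mer.
#' @export
junction_context <- function(circle, k = 8) {
  s <- circle$sequence
  n <- nchar(s)
  paste0(substr0(s, n - k, n), substr0(s, 0, k))
}

#' Label every precursor position by its region
#'
#' Positions in the homology arms, IRES and GOI take their segment label;
#' positions in the exon intervals are labelled E1/E2 (exon labels take
#' precedence over P-domain annotations); remaining intron positions take the
#' domain label covering their GII coordinate, with P-domains winning over
#' other annotations and `intron-other` as the fallback.
#'
#' @param layout a `pie_layout`.
#' @param intron the [intron_spec()] the layout was built from.
#' @return character vector of labels, one per precursor position.
#' @export
annotate_regions <- function(layout, intron) {
  plen <- nchar(layout$precursor_sequence)
  labels <- rep(NA_character_, plen)
  seg <- layout$segments
  for (k in seq_len(nrow(seg))) {
    if (seg$end[k] > seg$start[k] && seg$role[k] %in% c("H1", "IRES", "GOI", "H2"))
      labels[(seg$start[k] + 1L):seg$end[k]] <- seg$role[k]
  }
  if (diff(layout$e1_interval) > 0)
    labels[(layout$e1_interval[1] + 1L):layout$e1_interval[2]] <- "E1"
  if (diff(layout$e2_interval) > 0)
    labels[(layout$e2_interval[1] + 1L):layout$e2_interval[2]] <- "E2"
  todo <- which(is.na(labels))
  if (length(todo)) {
    gii <- layout$gii_map[todo]
    dom <- intron$domains
    is_p <- grepl("^P[1-9]$", dom$label)
    dom <- dom[order(!is_p), , drop = FALSE] # P-domains take precedence
    lab <- rep("intron-other", length(todo))
    assigned <- rep(FALSE, length(todo))
    for (k in seq_len(nrow(dom))) {
      hit <- !assigned & !is.na(gii) & gii >= dom$start[k] & gii < dom$end[k]
      lab[hit] <- dom$label[k]
      assigned <- assigned | hit
    }
    labels[todo] <- lab
  }
  labels
}

#' Linear splicing product of a native group I intron
#'
#' In the GII context splicing excises the intron and ligates the exons,
#' producing the linear E1-E2 product (the species checked as a gel band).
#'
#' @param intron an [intron_spec()] (used for context only).
#' @param e1,e2 exon sequences.
#' @return character, the ligated E1-E2 sequence.
#' @export
splice_gii <- function(intron, e1, e2) {
  paste0(norm_seq(e1), norm_seq(e2))
}

#' Serialize a PIE layout to a TSV segment table
#'
#' Writes the segment table with the exon intervals and the contiguous
#' blocks of `gii_map` recorded as comment lines, so the layout can be
#' reconstructed by [read_pie_layout()]. The precursor sequence itself is
#' written to FASTA with [write_fasta()] if `fasta` is given.
#'
#' @param layout a `pie_layout`.
#' @param path output TSV path.
#' @param fasta optional FASTA path for the precursor sequence.
#' @return invisibly, `path`.
#' @export
write_pie_layout <- function(layout, path, fasta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# circpie pie_layout name=%s", layout$intron_name), con)
  writeLines(sprintf("# e1_interval=%d,%d", layout$e1_interval[1], layout$e1_interval[2]), con)
  writeLines(sprintf("# e2_interval=%d,%d", layout$e2_interval[1], layout$e2_interval[2]), con)
  m <- layout$gii_map
  runs <- which(!is.na(m))
  if (length(runs)) {
    brk <- c(0L, which(diff(runs) != 1L | diff(m[runs]) != 1L), length(runs))
    for (b in seq_len(length(brk) - 1L)) {
      idx <- runs[(brk[b] + 1L):brk[b + 1L]]
      writeLines(sprintf("# gii_block=%d,%d,%d", idx[1] - 1L,
                         idx[length(idx)], m[idx[1]]), con)
    }
  }
  writeLines(sprintf("# precursor=%s", layout$precursor_sequence), con)
  utils::write.table(layout$segments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta))
    write_fasta(setNames(layout$precursor_sequence, layout$intron_name), fasta)
  invisible(path)
}

#' Read a PIE layout written by [write_pie_layout()]
#'
#' @param path TSV path.
#' @return a `pie_layout`.
#' @export
read_pie_layout <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(lines, "#")]
  getv <- function(key) sub(paste0("^# ", key, "="), "", com[grepl(paste0("^# ", key, "="), com)])
  iv <- function(key) as.integer(strsplit(getv(key)[1], ",")[[1]])
  precursor <- getv("precursor")[1]
  segments <- utils::read.table(path, sep = "\t", header = TRUE,
                                comment.char = "#", stringsAsFactors = FALSE)
  gii_map <- rep(NA_integer_, nchar(precursor))
  for (blk in getv("gii_block")) {
    v <- as.integer(strsplit(blk, ",")[[1]])
    if (v[2] > v[1]) gii_map[(v[1] + 1L):v[2]] <- v[3] + 0:(v[2] - v[1] - 1L)
  }
  nm <- sub("^# circpie pie_layout name=", "",
            com[grepl("pie_layout name=", com)])[1]
  structure(list(segments = segments,
                 e1_interval = iv("e1_interval"),
                 e2_interval = iv("e2_interval"),
                 precursor_sequence = precursor,
                 gii_map = gii_map,
                 intron_name = nm,
                 gii_e1 = NULL, gii_e2 = NULL, gii_intron = NULL),
            class = "pie_layout")
}
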