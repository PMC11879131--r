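# CIGAR/MD alignment walking. All event placement rules used by the
# mutational-profiling and junction-error modules live here:
#   - a mismatch is placed at its own reference position;
#   - an insertion is one event at the reference position immediately 5' of
#     the inserted bases;
#   - a deletion is one event at the reference position immediately 5' of the
#     deleted block (`del_anchor`), while the deleted reference positions
#     themselves are reported separately (`del_span`) and are not counted as
#     covered.

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

# reference-consuming span of a CIGAR (M/=/X/D/N)
cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
}

# Walk one alignment. Returns 0-based reference positions:
#   cover      - positions aligned to read bases (M/=/X)
#   mism       - mismatch positions (from MD, or SEQ-vs-reference fallback)
#   ins_anchor - one position per insertion, immediately 5' of the event
#   del_anchor - one position per deletion, immediately 5' of the event
#   del_span   - every deleted reference position
# An anchor falling before the alignment start (event at the very first
# aligned base) is clamped to the alignment start.
walk_alignment <- function(pos, cigar, md = NA_character_, seq = NA_character_,
                           reference = NULL) {
  cg <- parse_cigar(cigar)
  cover <- integer(0)
  ins_anchor <- integer(0)
  del_anchor <- integer(0)
  del_span <- integer(0)
  ref_cursor <- pos
  qry_cursor <- 0L # 0-based offset into SEQ
  qry_of_cover <- integer(0)
  for (k in seq_along(cg$op)) {
    n <- cg$len[k]
    switch(cg$op[k],
      "M" = , "=" = , "X" = {
        cover <- c(cover, ref_cursor + 0:(n - 1L))
        qry_of_cover <- c(qry_of_cover, qry_cursor + 0:(n - 1L))
        ref_cursor <- ref_cursor + n
        qry_cursor <- qry_cursor + n
      },
      "I" = {
        ins_anchor <- c(ins_anchor, max(ref_cursor - 1L, pos))
        qry_cursor <- qry_cursor + n
      },
      "D" = {
        del_anchor <- c(del_anchor, max(ref_cursor - 1L, pos))
        del_span <- c(del_span, ref_cursor + 0:(n - 1L))
        ref_cursor <- ref_cursor + n
      },
      "N" = {
        ref_cursor <- ref_cursor + n
      },
      "S" = {
        qry_cursor <- qry_cursor + n
      },
      "H" = NULL,
      "P" = NULL,
      stop("unsupported CIGAR op: ", cg$op[k])
    )
  }
  mism <- if (!is.na(md)) {
    mismatches_from_md(md, cover)
  } else if (!is.null(reference) && !is.na(seq) && seq != "*") {
    read_bases <- substring(seq, qry_of_cover + 1L, qry_of_cover + 1L)
    ref_bases <- substring(reference, cover + 1L, cover + 1L)
    cover[read_bases != ref_bases]
  } else {
    stop("cannot recover mismatches: no MD tag and no reference sequence")
  }
  list(cover = cover, mism = mism, ins_anchor = ins_anchor,
       del_anchor = del_anchor, del_span = del_span)
}

# MD walks the aligned (M) bases only; deletions appear as ^BASES and do not
# consume aligned positions. `cover` is the in-order vector of reference
# positions of the M bases.
mismatches_from_md <- function(md, cover) {
  tokens <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  i <- 0L # aligned bases consumed
  mism <- integer(0)
  for (tok in tokens) {
    first <- substr(tok, 1, 1)
    if (first == "^") {
      # deletion block: reference-only, no aligned base consumed
    } else if (first >= "0" && first <= "9") {
      i <- i + as.integer(tok)
    } else {
      mism <- c(mism, cover[i + 1L])
      i <- i + 1L
    }
  }
  if (i > length(cover)) stop("MD string inconsistent with CIGAR: ", md)
  mism
}

# Build an MD string for a full-match alignment with mismatches at the given
# 0-based offsets (relative to the alignment), given the reference bases
# there.
md_from_mismatches <- function(aln_len, offsets, ref_bases) {
  if (!length(offsets)) return(as.character(aln_len))
  o <- order(offsets)
  offsets <- offsets[o]
  ref_bases <- ref_bases[o]
  gaps <- diff(c(-1L, offsets)) - 1L
  paste0(paste0(gaps, ref_bases, collapse = ""), aln_len - offsets[length(offsets)] - 1L)
}
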