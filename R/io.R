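# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA (via Biostrings), a SAM v1 text subset with MD/SA tags, BED-like
# domain tables, and TSV outputs with provenance headers.
#
# Coordinate convention: SAM positions are converted 1-based -> 0-based at
# this boundary, exactly once; BED input is already 0-based half-open and is
# passed through unchanged. Everything downstream is 0-based half-open.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is converted to T (all downstream analysis
#' is on DNA-alphabet strings). Multi-line entries are joined; names are
#' truncated at the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; empty vector for an empty
#'   file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- norm_seq(as.character(set))
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) stop("duplicate FASTA names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  setNames(seqs, nms)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a BED-like domain annotation table
#'
#' Expects at least four columns (chrom, start, end, name), tab-separated,
#' 0-based half-open coordinates. Returns the domain table used by
#' [intron_spec()].
#'
#' @param path path to the BED file.
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
read_bed_domains <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 4) stop("BED domain file needs chrom/start/end/name columns")
  data.frame(label = as.character(bed[[4]]),
             start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}

# --- SAM -------------------------------------------------------------------

SAM_FLAG_UNMAPPED <- 4L
SAM_FLAG_REVERSE <- 16L
SAM_FLAG_SECONDARY <- 256L
SAM_FLAG_SUPPLEMENTARY <- 2048L

sam_columns <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "seq", "md", "sa")

#' Construct a SAM record table
#'
#' Internal canonical representation of alignments: one row per SAM line with
#' 0-based leftmost positions, the MD and SA tag payloads when present, and
#' decoded flag columns (`mapped`, `strand`, `primary`, `supplementary`).
#'
#' @param qname,flag,rname,pos,mapq,cigar,seq,md,sa record fields; `pos` is
#'   0-based; `md`/`sa` may be NA.
#' @return data.frame of class `sam_records`.
#' @export
sam_records <- function(qname = character(0), flag = integer(0),
                        rname = character(0), pos = integer(0),
                        mapq = integer(0), cigar = character(0),
                        seq = character(0), md = NA_character_,
                        sa = NA_character_) {
  n <- length(qname)
  df <- data.frame(qname = as.character(qname),
                   flag = as.integer(flag),
                   rname = as.character(rname),
                   pos = as.integer(pos),
                   mapq = as.integer(mapq),
                   cigar = as.character(cigar),
                   seq = if (n && length(seq)) as.character(seq) else rep("*", n),
                   md = if (n) rep_len(as.character(md), n) else character(0),
                   sa = if (n) rep_len(as.character(sa), n) else character(0),
                   stringsAsFactors = FALSE)
  decorate_sam(df)
}

decorate_sam <- function(df) {
  df$mapped <- bitwAnd(df$flag, SAM_FLAG_UNMAPPED) == 0L
  df$strand <- ifelse(bitwAnd(df$flag, SAM_FLAG_REVERSE) != 0L, "-", "+")
  df$supplementary <- bitwAnd(df$flag, SAM_FLAG_SUPPLEMENTARY) != 0L
  df$secondary <- bitwAnd(df$flag, SAM_FLAG_SECONDARY) != 0L
  df$primary <- !df$supplementary & !df$secondary
  class(df) <- c("sam_records", "data.frame")
  df
}

#' Read a plain-text SAM file
#'
#' Parses the SAM v1 subset the pipeline needs: mandatory fields plus the
#' `MD:Z` and `SA:Z` optional tags. SAM's 1-based leftmost positions are
#' converted to 0-based here and nowhere else. Unmapped records are retained
#' with `mapped = FALSE`.
#'
#' @param path path to a SAM text file (header lines are skipped).
#' @return a `sam_records` data.frame.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  if (!length(body)) return(sam_records())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    bad <- body[which(nf < 11)[1]]
    stop(sprintf("malformed SAM record at line %d: fewer than 11 fields", bad))
  }
  pos1 <- suppressWarnings(vapply(fields, function(f) as.integer(f[4]), integer(1)))
  flag <- suppressWarnings(vapply(fields, function(f) as.integer(f[2]), integer(1)))
  if (anyNA(pos1) || anyNA(flag)) {
    bad <- body[which(is.na(pos1) | is.na(flag))[1]]
    stop(sprintf("malformed SAM record at line %d: non-numeric FLAG/POS", bad))
  }
  get_tag <- function(f, prefix) {
    if (length(f) <= 11) return(NA_character_)
    tg <- f[12:length(f)]
    hit <- tg[startsWith(tg, prefix)]
    if (length(hit)) substring(hit[1], nchar(prefix) + 1L) else NA_character_
  }
  sam_records(qname = vapply(fields, `[`, "", 1),
              flag = flag,
              rname = vapply(fields, `[`, "", 3),
              pos = pos1 - 1L,
              mapq = suppressWarnings(vapply(fields, function(f) as.integer(f[5]), integer(1))),
              cigar = vapply(fields, `[`, "", 6),
              seq = vapply(fields, `[`, "", 10),
              md = vapply(fields, get_tag, "", "MD:Z:"),
              sa = vapply(fields, get_tag, "", "SA:Z:"))
}

#' Write SAM records to a plain-text SAM file
#'
#' Emits a minimal header (`@HD`, one `@SQ` per reference) followed by the
#' records; positions are converted back to 1-based on output.
#'
#' @param records a `sam_records` data.frame.
#' @param path output path.
#' @param ref_lengths named integer vector of reference lengths for `@SQ`
#'   lines.
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, path, ref_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  if (nrow(records)) {
    tags <- character(nrow(records))
    has_md <- !is.na(records$md)
    has_sa <- !is.na(records$sa)
    tags[has_md] <- paste0("\tMD:Z:", records$md[has_md])
    tags[has_sa] <- paste0(tags[has_sa], "\tSA:Z:", records$sa[has_sa])
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                    records$qname, records$flag, records$rname,
                    records$pos + 1L, records$mapq, records$cigar,
                    records$seq, tags)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse an SA:Z tag payload into its alignment entries
#'
#' The SA tag holds semicolon-terminated entries
#' `rname,pos,strand,CIGAR,mapQ,NM`. Positions are converted to 0-based.
#'
#' @param sa the tag payload (the part after `SA:Z:`), or NA.
#' @return data.frame with one row per entry (zero rows for NA/empty); throws
#'   on a malformed entry.
#' @export
parse_sa_tag <- function(sa) {
  empty <- data.frame(rname = character(0), pos = integer(0),
                      strand = character(0), cigar = character(0),
                      mapq = integer(0), nm = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(sa) || !nzchar(sa)) return(empty)
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  if (!length(entries)) return(empty)
  parts <- strsplit(entries, ",", fixed = TRUE)
  if (any(lengths(parts) < 4)) stop("malformed SA entry: ", sa)
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  if (anyNA(pos)) stop("malformed SA entry: ", sa)
  mapq <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 5) p[5] else NA_character_, "")))
  nm <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 6) p[6] else NA_character_, "")))
  data.frame(rname = vapply(parts, `[`, "", 1),
             pos = pos - 1L,
             strand = vapply(parts, `[`, "", 3),
             cigar = vapply(parts, `[`, "", 4),
             mapq = mapq, nm = nm,
             stringsAsFactors = FALSE)
}

#' Read a pileup table from TSV
#'
#' Expected columns: `position` (0-based), `ref`, `A`, `C`, `G`, `T`, and
#' optionally `ins`, `del`.
#'
#' @param path path to the TSV file (comment lines starting with `#` are
#'   ignored).
#' @return data.frame.
#' @export
read_pileup <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a table to TSV with a provenance comment header
#'
#' Every pipeline output TSV carries a `#` comment recording the package
#' version and the parameters that produced it, followed by a header line.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list recorded in the provenance line.
#' @return invisibly, `path`.
#' @export
write_tsv_provenance <- function(df, path, params = list()) {
  ver <- as.character(utils::packageVersion("circpie"))
  params <- params[!vapply(params, is.null, TRUE)]
  ptxt <- if (length(params))
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(x) paste(x, collapse = ","), "")),
          collapse = " ")
  else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# circpie %s %s", ver, ptxt), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
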