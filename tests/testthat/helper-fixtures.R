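# Shared fixtures: a deterministic toy group I intron construct, SAM record
# builders, a random-construct generator, and an independent brute-force
# reference implementation of the SPLASH pipeline used as oracle.

# Toy GII: E1 (4 nt) + 40-nt intron + E2 (4 nt), explicit strings so
# expected values can be derived by hand concatenation.
TOY_E1 <- "ACGT"
TOY_INTRON <- "TTGACCTGAGCAATTGCCAAGGTTCCAAGGTTGGCCAATT" # 40 nt
TOY_E2 <- "GGCC"
TOY_GII <- paste0(TOY_E1, TOY_INTRON, TOY_E2) # 48 nt; intron = [4, 44)

toy_domains <- function() {
  # GII coordinates; P6 = [20, 28) so the default split point is 24
  data.frame(label = c("P2", "P6", "P7", "P9"),
             start = c(6L, 20L, 28L, 36L),
             end = c(12L, 28L, 34L, 42L),
             stringsAsFactors = FALSE)
}

toy_intron <- function() intron_spec("toy", TOY_GII, toy_domains())

toy_layout <- function(ires = "", goi = "AACCGG", h1 = "", h2 = "") {
  build_pie(toy_intron(), e1 = c(0, 4), e2 = c(44, 48),
            ires = ires, goi = goi, h1 = h1, h2 = h2)
}

# A larger layout whose precursor is several hundred nt, for window-level
# work: 12-nt homology arms, 20-nt IRES, 120-nt GOI.
big_layout <- function() {
  set.seed(99)
  goi <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  build_pie(toy_intron(), e1 = c(0, 4), e2 = c(44, 48),
            ires = paste(rep("ACGT", 5), collapse = ""), goi = goi,
            h1 = "GGGGGGGGGGGG", h2 = "CCCCCCCCCCCC")
}

# record builders -----------------------------------------------------------

chim_pair <- function(qname, a1, a2, mapq = 60L, rname = "precursor",
                      flag1 = 0L) {
  l1 <- a1[2] - a1[1]; l2 <- a2[2] - a2[1]
  cig1 <- sprintf("%dM%dS", l1, l2)
  cig2 <- sprintf("%dS%dM", l1, l2)
  strand <- if (bitwAnd(flag1, 16L)) "-" else "+"
  sam_records(qname = c(qname, qname), flag = c(flag1, flag1 + 2048L),
              rname = rname, pos = c(a1[1], a2[1]), mapq = mapq,
              cigar = c(cig1, cig2), seq = "*",
              sa = c(sprintf("%s,%d,%s,%s,%d,0;", rname, a2[1] + 1L, strand, cig2, mapq),
                     sprintf("%s,%d,%s,%s,%d,0;", rname, a1[1] + 1L, strand, cig1, mapq)))
}

linear_read <- function(qname, pos, len = 20L, mapq = 60L,
                        rname = "precursor", flag = 0L) {
  sam_records(qname = qname, flag = flag, rname = rname, pos = pos,
              mapq = mapq, cigar = sprintf("%dM", len), seq = "*")
}

bind_sam <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("sam_records", "data.frame")
  out
}

# random construct for property tests ---------------------------------------

random_construct <- function() {
  e1_len <- sample(3:6, 1); e2_len <- sample(3:6, 1)
  intron_len <- sample(30:60, 1)
  gii <- paste(sample(c("A", "C", "G", "T"), e1_len + intron_len + e2_len,
                      replace = TRUE), collapse = "")
  istart <- e1_len; iend <- e1_len + intron_len
  p6_start <- istart + sample(5:(intron_len - 10), 1)
  p6_end <- p6_start + sample(4:8, 1)
  dom <- data.frame(label = "P6", start = p6_start, end = min(p6_end, iend - 1L),
                    stringsAsFactors = FALSE)
  it <- intron_spec("rand", gii, dom)
  lay <- build_pie(it, e1 = c(0, e1_len), e2 = c(iend, iend + e2_len),
                   ires = paste(sample(c("A", "C", "G", "T"), sample(0:12, 1),
                                       replace = TRUE), collapse = ""),
                   goi = paste(sample(c("A", "C", "G", "T"), sample(0:30, 1),
                                      replace = TRUE), collapse = ""),
                   h1 = paste(rep("G", sample(0:8, 1)), collapse = ""),
                   h2 = paste(rep("C", sample(0:8, 1)), collapse = ""))
  list(intron = it, layout = lay,
       e1_len = e1_len, e2_len = e2_len, intron_len = intron_len)
}

# independent brute-force SPLASH reference ----------------------------------
# Enumerates records directly with plain loops; shares no code with the
# package implementation beyond the record field names.

brute_cigar_span <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  total <- 0L
  for (k in seq_along(ops))
    if (ops[k] %in% c("M", "=", "X", "D", "N")) total <- total + lens[k]
  total
}

brute_splash <- function(records, layout, window = 10, min_mapq = 20,
                         min_arm = 10, tol = 5) {
  df <- as.data.frame(records)
  n <- nrow(df)
  is_supp <- bitwAnd(df$flag, 2048L) != 0L
  is_sec <- bitwAnd(df$flag, 256L) != 0L
  is_unmapped <- bitwAnd(df$flag, 4L) != 0L
  is_minus <- bitwAnd(df$flag, 16L) != 0L
  # dedup: first mapped primary per (rname,pos,strand,cigar) key wins
  seen <- character(0)
  keep <- rep(TRUE, n)
  dropped_q <- character(0)
  for (i in seq_len(n)) {
    if (is_supp[i] || is_sec[i] || is_unmapped[i]) next
    k <- paste(df$rname[i], df$pos[i], ifelse(is_minus[i], "-", "+"), df$cigar[i])
    if (k %in% seen) {
      keep[i] <- FALSE
      dropped_q <- c(dropped_q, df$qname[i])
    } else seen <- c(seen, k)
  }
  for (i in seq_len(n))
    if ((is_supp[i] || is_sec[i]) && df$qname[i] %in% dropped_q) keep[i] <- FALSE
  df <- df[keep, , drop = FALSE]
  is_supp <- is_supp[keep]; is_sec <- is_sec[keep]
  is_unmapped <- is_unmapped[keep]; is_minus <- is_minus[keep]
  # chimera extraction
  total_mapped <- 0L
  arms <- list()
  for (i in seq_len(nrow(df))) {
    if (is_supp[i] || is_sec[i] || is_unmapped[i]) next
    total_mapped <- total_mapped + 1L
    sa <- df$sa[i]
    if (is.na(sa) || !nzchar(sa) || is_minus[i]) next
    entries <- strsplit(sa, ";")[[1]]
    entries <- entries[nzchar(entries)]
    if (length(entries) != 1) next
    p <- strsplit(entries, ",")[[1]]
    if (p[1] != df$rname[i] || p[3] != "+") next
    a1 <- c(df$pos[i], df$pos[i] + brute_cigar_span(df$cigar[i]))
    a2 <- c(as.integer(p[2]) - 1L,
            as.integer(p[2]) - 1L + brute_cigar_span(p[4]))
    if (a2[1] < a1[1]) { tmp <- a1; a1 <- a2; a2 <- tmp }
    mq <- min(df$mapq[i], as.integer(p[5]))
    arms[[length(arms) + 1L]] <- list(a1 = a1, a2 = a2, mapq = mq)
  }
  # filter + bin
  e1_end <- layout$e1_interval[2]; e2_start <- layout$e2_interval[1]
  tallies <- list()
  for (ch in arms) {
    if (ch$mapq <= min_mapq) next
    if (ch$a1[2] - ch$a1[1] <= min_arm) next
    if (ch$a2[2] - ch$a2[1] <= min_arm) next
    if ((abs(ch$a1[2] - e1_end) <= tol && abs(ch$a2[1] - e2_start) <= tol) ||
        (abs(ch$a1[1] - e2_start) <= tol && abs(ch$a2[2] - e1_end) <= tol)) next
    wi <- ch$a1[1] %/% window; wj <- ch$a2[1] %/% window
    key <- paste(min(wi, wj), max(wi, wj))
    tallies[[key]] <- (tallies[[key]] %||% 0L) + 1L
  }
  tallies <- tallies[vapply(tallies, function(x) x >= 2L, TRUE)]
  list(counts = tallies, total_mapped = total_mapped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical sorted key->count table for comparing map outputs
sorted_counts <- function(keys, values) {
  keys <- as.character(keys %||% character(0))
  df <- data.frame(key = keys, count = as.integer(values),
                   stringsAsFactors = FALSE)
  df <- df[order(df$key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random SAM fixture for the oracle-equivalence check
random_sam_fixture <- function(layout, n_max = 50) {
  plen <- nchar(layout$precursor_sequence)
  recs <- list()
  n <- 0L
  i <- 0L
  while (n < sample(10:n_max, 1)) {
    i <- i + 1L
    kind <- sample(c("chim", "chim", "linear", "junction", "lowq", "shortarm",
                     "minus", "multisa"), 1)
    mapq <- sample(c(15L, 20L, 21L, 40L, 60L), 1)
    l1 <- sample(c(8L, 10L, 11L, 15L, 25L), 1)
    l2 <- sample(c(8L, 10L, 11L, 15L, 25L), 1)
    p1 <- sample(0:(plen - 40L), 1); p2 <- sample(0:(plen - 40L), 1)
    if (kind == "linear") {
      recs[[i]] <- linear_read(sprintf("r%03d", i), p1, len = l1, mapq = mapq)
      n <- n + 1L
    } else if (kind == "minus") {
      recs[[i]] <- chim_pair(sprintf("r%03d", i), c(p1, p1 + l1), c(p2, p2 + l2),
                             mapq = mapq, flag1 = 16L)
      n <- n + 2L
    } else if (kind == "multisa") {
      r <- chim_pair(sprintf("r%03d", i), c(p1, p1 + l1), c(p2, p2 + l2),
                     mapq = mapq)
      r$sa[1] <- paste0(r$sa[1], "precursor,5,+,10M,60,0;")
      recs[[i]] <- r
      n <- n + 2L
    } else if (kind == "junction") {
      e1e <- layout$e1_interval[2]; e2s <- layout$e2_interval[1]
      recs[[i]] <- chim_pair(sprintf("r%03d", i),
                             c(e2s + sample(-2:2, 1), e2s + 20L),
                             c(e1e - 20L, e1e + sample(-2:2, 1)),
                             mapq = 60L)
      n <- n + 2L
    } else {
      a1 <- sort(c(p1, p2))[1]; a2 <- sort(c(p1, p2))[2]
      recs[[i]] <- chim_pair(sprintf("r%03d", i), c(a1, a1 + l1), c(a2, a2 + l2),
                             mapq = if (kind == "lowq") sample(c(10L, 20L), 1) else mapq)
      n <- n + 2L
    }
    # occasional exact PCR duplicate of the previous record pair
    if (runif(1) < 0.2 && !is.null(recs[[i]])) {
      i <- i + 1L
      dup <- recs[[i - 1L]]
      dup$qname <- paste0(dup$qname, "d")
      recs[[i]] <- dup
      n <- n + nrow(dup)
    }
  }
  do.call(bind_sam, recs[!vapply(recs, is.null, TRUE)])
}
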