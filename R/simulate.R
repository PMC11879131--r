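# Seeded simulators for every read-level input the pipeline consumes:
# mutational-profiling channels, SPLASH chimeric libraries, randomized-exon
# (N60) amplicons, junction-error reads and variant pileups. Each generator
# is a pure function of its inputs and a mandatory seed (RNG state is
# restored afterwards), and emits the same `sam_records`/character/TSV
# structures the consuming parsers read, so generated data round-trips
# through write_sam()/read_sam().

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "",
         USE.NAMES = FALSE)
}

#' Simulate SHAPE-MaP profiling reads for the three channels
#'
#' Generates full-length reads whose per-position substitution probabilities
#' follow the probing model: untreated channel mutates at the background
#' rate `eps_u`, the denatured control at rate `d`, and the modified (NAI)
#' channel at `min(1, eps_u + k * truth[i] * d)`, so the expected recovered
#' raw reactivity is proportional to the true reactivity. Mutations are
#' encoded in SEQ and the MD tag (CIGAR is full-match).
#'
#' @param ref reference sequence.
#' @param truth non-negative true reactivity vector, one value per
#'   reference position.
#' @param depth reads per channel (full-length reads, so read count equals
#'   per-position depth).
#' @param eps_u untreated background mutation rate (default 0.005).
#' @param d denatured-control mutation rate (default 0.08).
#' @param k modification gain (default 1).
#' @param seed mandatory RNG seed.
#' @param ref_name reference name for the records (default "ref").
#' @return named list of three `sam_records` tables: `modified`,
#'   `untreated`, `denatured`.
#' @export
simulate_profiling_reads <- function(ref, truth, depth = 500, eps_u = 0.005,
                                     d = 0.08, k = 1, seed,
                                     ref_name = "ref") {
  ref <- norm_seq(ref[[1]])
  L <- nchar(ref)
  stopifnot(length(truth) == L, all(truth >= 0))
  p_mod <- eps_u + k * truth * d
  if (any(p_mod > 1)) {
    warning("modified-channel probabilities > 1 clipped")
    p_mod <- pmin(p_mod, 1)
  }
  probs <- list(modified = p_mod,
                untreated = rep(eps_u, L),
                denatured = rep(d, L))
  ref_chars <- strsplit(ref, "")[[1]]
  with_seed(seed, {
    lapply(setNames(names(probs), names(probs)), function(ch) {
      p <- probs[[ch]]
      mut <- matrix(stats::runif(depth * L), depth, L) <
        matrix(p, depth, L, byrow = TRUE)
      seqs <- character(depth)
      mds <- character(depth)
      for (r in seq_len(depth)) {
        pos <- which(mut[r, ])
        if (length(pos)) {
          chars <- ref_chars
          chars[pos] <- other_base(ref_chars[pos])
          seqs[r] <- paste(chars, collapse = "")
          mds[r] <- md_from_mismatches(L, pos - 1L, ref_chars[pos])
        } else {
          seqs[r] <- ref
          mds[r] <- as.character(L)
        }
      }
      sam_records(qname = sprintf("%s_%06d", ch, seq_len(depth)),
                  flag = 0L, rname = ref_name, pos = 0L, mapq = 60L,
                  cigar = paste0(L, "M"), seq = seqs, md = mds)
    })
  })
}

#' Simulate a SPLASH chimeric-read library with planted interactions
#'
#' Draws chimeras from the planted arm-pair interactions proportionally to
#' their weights, jittering arm starts by up to `jitter` nt and drawing arm
#' lengths uniformly from `arm_len_range`; a `noise_fraction` of chimeras
#' instead places both arms uniformly on the reference. Each chimera is
#' emitted as a primary alignment with an SA tag plus the matching
#' supplementary line; `n_linear` ordinary (non-chimeric) reads are added,
#' and `Binomial(n_reads + n_linear, duplicate_rate)` PCR-duplicate copies
#' of random reads are appended on top.
#'
#' @param ref_length reference length in nt.
#' @param interactions list of `list(arm1 = c(start, end), arm2 = c(start,
#'   end), weight = w)` with intervals inside the reference.
#' @param n_reads number of chimeric reads (default 500).
#' @param noise_fraction fraction of chimeras with uniform random arms
#'   (default 0.1).
#' @param duplicate_rate PCR duplicate injection rate (default 0).
#' @param n_linear number of non-chimeric reads (default 100).
#' @param jitter maximal arm-start jitter in nt (default 3).
#' @param arm_len_range inclusive range of arm lengths (default 15–35).
#' @param seed mandatory RNG seed.
#' @param ref_name reference name (default "precursor").
#' @return a `sam_records` table.
#' @export
simulate_chimeric_library <- function(ref_length, interactions, n_reads = 500,
                                      noise_fraction = 0.1,
                                      duplicate_rate = 0, n_linear = 100,
                                      jitter = 3, arm_len_range = c(15, 35),
                                      seed, ref_name = "precursor") {
  for (it in interactions) {
    check_interval(it$arm1, ref_length, "interaction arm1")
    check_interval(it$arm2, ref_length, "interaction arm2")
    if (is.null(it$weight) || it$weight <= 0) stop("interaction weights must be > 0")
  }
  with_seed(seed, {
    n_noise <- round(n_reads * noise_fraction)
    n_planted <- n_reads - n_noise
    arm_len <- function(n) sample(arm_len_range[1]:arm_len_range[2], n, replace = TRUE)
    clamp <- function(s, len) pmax(0L, pmin(as.integer(s), ref_length - len))
    rows <- list()
    if (n_reads > 0) {
      which_int <- if (length(interactions) && n_planted > 0)
        sample(seq_along(interactions), n_planted, replace = TRUE,
               prob = vapply(interactions, `[[`, 0, "weight"))
      else integer(0)
      a1s <- integer(n_reads); a2s <- integer(n_reads)
      l1 <- arm_len(n_reads); l2 <- arm_len(n_reads)
      for (i in seq_len(n_planted)) {
        it <- interactions[[which_int[i]]]
        a1s[i] <- clamp(it$arm1[1] + sample(-jitter:jitter, 1), l1[i])
        a2s[i] <- clamp(it$arm2[1] + sample(-jitter:jitter, 1), l2[i])
      }
      if (n_noise > 0) {
        idx <- n_planted + seq_len(n_noise)
        a1s[idx] <- clamp(sample.int(ref_length, n_noise, replace = TRUE) - 1L, l1[idx])
        a2s[idx] <- clamp(sample.int(ref_length, n_noise, replace = TRUE) - 1L, l2[idx])
      }
      swap <- a2s < a1s
      tmp <- a1s[swap]; a1s[swap] <- a2s[swap]; a2s[swap] <- tmp
      tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
      for (i in seq_len(n_reads)) {
        qn <- sprintf("chim_%06d", i)
        cig1 <- paste0(l1[i], "M", l2[i], "S")
        cig2 <- paste0(l1[i], "S", l2[i], "M")
        sa1 <- sprintf("%s,%d,+,%s,60,0;", ref_name, a2s[i] + 1L, cig2)
        sa2 <- sprintf("%s,%d,+,%s,60,0;", ref_name, a1s[i] + 1L, cig1)
        rows[[length(rows) + 1L]] <- data.frame(
          qname = qn, flag = c(0L, 2048L), rname = ref_name,
          pos = c(a1s[i], a2s[i]), mapq = 60L, cigar = c(cig1, cig2),
          seq = "*", md = NA_character_, sa = c(sa1, sa2),
          stringsAsFactors = FALSE)
      }
    }
    if (n_linear > 0) {
      llen <- arm_len(n_linear)
      lpos <- clamp(sample.int(ref_length, n_linear, replace = TRUE) - 1L, llen)
      rows[[length(rows) + 1L]] <- data.frame(
        qname = sprintf("lin_%06d", seq_len(n_linear)), flag = 0L,
        rname = ref_name, pos = lpos, mapq = 60L,
        cigar = paste0(llen, "M"), seq = "*", md = NA_character_,
        sa = NA_character_, stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(qname = character(0), flag = integer(0),
                    rname = character(0), pos = integer(0),
                    mapq = integer(0), cigar = character(0),
                    seq = character(0), md = character(0),
                    sa = character(0), stringsAsFactors = FALSE)
    if (duplicate_rate > 0 && nrow(df)) {
      reads <- unique(df$qname)
      n_dup <- stats::rbinom(1, length(reads), duplicate_rate)
      if (n_dup > 0) {
        src <- sample(reads, n_dup, replace = TRUE)
        dup_rows <- do.call(rbind, lapply(seq_along(src), function(i) {
          cp <- df[df$qname == src[i], , drop = FALSE]
          cp$qname <- sprintf("dup_%06d", i)
          cp
        }))
        df <- rbind(df, dup_rows)
      }
    }
    sam_records(qname = df$qname, flag = df$flag, rname = df$rname,
                pos = df$pos, mapq = df$mapq, cigar = df$cigar,
                seq = df$seq, md = df$md, sa = df$sa)
  })
}

#' Simulate a randomized-exon (N60) amplicon library
#'
#' Each read is random-prefix | flank5 | insert | flank3 | random-suffix,
#' with the insert uniform over ACGT except at the constrained positions; a
#' `length_fail_fraction` of reads carry 59- or 61-nt inserts as
#' length-failure spike-ins.
#'
#' @param flank5,flank3 8-nt anchor sequences.
#' @param n_reads number of reads.
#' @param constraints named list/vector position -> base, 0-based positions
#'   in `[0, insert_length)`.
#' @param insert_length nominal insert length (default 60).
#' @param length_fail_fraction fraction of spike-in reads with 59/61-nt
#'   inserts (default 0).
#' @param flank_fail_fraction fraction of reads lacking the 5' flank
#'   (default 0).
#' @param prefix_range inclusive range of random prefix/suffix lengths
#'   (default 0–10).
#' @param seed mandatory RNG seed.
#' @return character vector of reads.
#' @export
simulate_n60_library <- function(flank5, flank3, n_reads,
                                 constraints = list(), insert_length = 60,
                                 length_fail_fraction = 0,
                                 flank_fail_fraction = 0,
                                 prefix_range = c(0, 10), seed) {
  flank5 <- norm_seq(flank5); flank3 <- norm_seq(flank3)
  cpos <- as.integer(names(constraints))
  cbase <- norm_seq(unlist(constraints, use.names = FALSE))
  if (length(cpos) && (any(cpos < 0) || any(cpos >= insert_length)))
    stop("constraint positions must lie in [0, insert_length)")
  with_seed(seed, {
    vapply(seq_len(n_reads), function(i) {
      len <- insert_length
      if (length_fail_fraction > 0 && stats::runif(1) < length_fail_fraction)
        len <- insert_length + sample(c(-1L, 1L), 1)
      ins <- strsplit(random_dna(len), "")[[1]]
      if (len == insert_length && length(cpos))
        ins[cpos + 1L] <- cbase
      f5 <- if (flank_fail_fraction > 0 && stats::runif(1) < flank_fail_fraction)
        "" else flank5
      paste0(random_dna(sample(prefix_range[1]:prefix_range[2], 1)),
             f5, paste(ins, collapse = ""), flank3,
             random_dna(sample(prefix_range[1]:prefix_range[2], 1)))
    }, "")
  })
}

#' Simulate reads with planted junction errors
#'
#' Full-length reads against a junction reference with independent planted
#' per-position mismatch and deletion events, for testing error-rate
#' recovery. Deletions are encoded in the CIGAR (single-base D ops),
#' mismatches in SEQ/MD.
#'
#' @param ref reference sequence.
#' @param mismatch_rates,deletion_rates numeric vectors (length of `ref`) of
#'   per-position event probabilities; scalars are recycled.
#' @param depth number of reads.
#' @param seed mandatory RNG seed.
#' @param ref_name reference name (default "junction").
#' @return a `sam_records` table.
#' @export
simulate_junction_reads <- function(ref, mismatch_rates = 0,
                                    deletion_rates = 0, depth = 1000, seed,
                                    ref_name = "junction") {
  ref <- norm_seq(ref[[1]])
  L <- nchar(ref)
  pm <- rep_len(mismatch_rates, L)
  pd <- rep_len(deletion_rates, L)
  ref_chars <- strsplit(ref, "")[[1]]
  with_seed(seed, {
    mm <- matrix(stats::runif(depth * L), depth, L) <
      matrix(pm, depth, L, byrow = TRUE)
    dd <- matrix(stats::runif(depth * L), depth, L) <
      matrix(pd, depth, L, byrow = TRUE)
    mm[dd] <- FALSE # a deleted base cannot also mismatch
    seqs <- character(depth); cigars <- character(depth); mds <- character(depth)
    for (r in seq_len(depth)) {
      delp <- which(dd[r, ])
      mmp <- which(mm[r, ])
      keep <- setdiff(seq_len(L), delp)
      chars <- ref_chars
      if (length(mmp)) chars[mmp] <- other_base(ref_chars[mmp])
      seqs[r] <- paste(chars[keep], collapse = "")
      if (!length(delp)) {
        cigars[r] <- paste0(L, "M")
        mds[r] <- md_from_mismatches(L, mmp - 1L, ref_chars[mmp])
      } else {
        # alternate M blocks and 1-base deletions
        blocks <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
        cig <- character(0)
        md <- character(0)
        prev_end <- 0L
        consumed <- 0L
        for (b in blocks) {
          if (b[1] > prev_end + 1L) {
            ndel <- b[1] - prev_end - 1L
            cig <- c(cig, paste0(ndel, "D"))
            md <- c(md, paste0("^", paste(ref_chars[(prev_end + 1L):(b[1] - 1L)],
                                          collapse = "")))
          }
          cig <- c(cig, paste0(length(b), "M"))
          bm <- intersect(b, mmp)
          md <- c(md, md_from_mismatches(length(b), match(bm, b) - 1L,
                                         ref_chars[bm]))
          prev_end <- b[length(b)]
          consumed <- consumed + length(b)
        }
        if (prev_end < L) {
          cig <- c(cig, paste0(L - prev_end, "D"))
          md <- c(md, paste0("^", paste(ref_chars[(prev_end + 1L):L], collapse = "")))
        }
        cigars[r] <- paste(cig, collapse = "")
        mds[r] <- paste(md, collapse = "")
      }
    }
    sam_records(qname = sprintf("jx_%06d", seq_len(depth)), flag = 0L,
                rname = ref_name, pos = 0L, mapq = 60L, cigar = cigars,
                seq = seqs, md = mds)
  })
}

#' Simulate a sequencing pileup with planted variants
#'
#' Per position the base counts are multinomial over depth, with the
#' reference base taking probability 1 - error_rate - planted_frequency,
#' each non-reference base error_rate / 3, and the planted alternate base
#' gaining its planted frequency.
#'
#' @param ref reference sequence.
#' @param variants list of `list(position = p, alt = "G", freq = f)` with
#'   frequencies in (0, 1); at most one per position.
#' @param depth reads per position.
#' @param error_rate per-base error rate (default 0.001).
#' @param seed mandatory RNG seed.
#' @return pileup data.frame: `position`, `ref`, `A`, `C`, `G`, `T`.
#' @export
simulate_pileup <- function(ref, variants = list(), depth = 2000,
                            error_rate = 0.001, seed) {
  ref <- norm_seq(ref[[1]])
  L <- nchar(ref)
  vpos <- vapply(variants, `[[`, 0, "position")
  if (anyDuplicated(vpos)) stop("overlapping variant specs at one position")
  for (v in variants) {
    if (v$freq <= 0 || v$freq >= 1) stop("variant frequencies must be in (0,1)")
    if (v$position < 0 || v$position >= L) stop("variant position out of range")
  }
  bases <- c("A", "C", "G", "T")
  ref_chars <- strsplit(ref, "")[[1]]
  with_seed(seed, {
    counts <- matrix(0L, L, 4, dimnames = list(NULL, bases))
    for (i in seq_len(L)) {
      p <- rep(error_rate / 3, 4)
      names(p) <- bases
      v <- variants[match(i - 1L, vpos)]
      vfreq <- 0
      if (!is.na(match(i - 1L, vpos))) {
        v <- variants[[match(i - 1L, vpos)]]
        p[norm_seq(v$alt)] <- p[norm_seq(v$alt)] + v$freq
        vfreq <- v$freq
      }
      p[ref_chars[i]] <- 1 - error_rate - vfreq
      counts[i, ] <- as.integer(stats::rmultinom(1, depth, p))
    }
    data.frame(position = seq_len(L) - 1L, ref = ref_chars,
               A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
               T = counts[, "T"], stringsAsFactors = FALSE)
  })
}
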