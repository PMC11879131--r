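# SPLASH chimeric-read pipeline: dedup, chimera extraction, filtering,
# binning/normalization, classification, differential testing.

test_that("records sharing position and CIGAR collapse to one read", {
  r <- linear_read("a", 100L)
  recs <- bind_sam(r, within(as.data.frame(r), qname <- "b"),
                   within(as.data.frame(r), qname <- "c"))
  dd <- dedupe_reads(recs)
  expect_equal(nrow(dd), 1)
  expect_equal(attr(dd, "n_removed"), 2L)
  # same CIGAR at a different position is not a duplicate
  recs2 <- bind_sam(linear_read("a", 100L), linear_read("b", 101L))
  expect_equal(nrow(dedupe_reads(recs2)), 2)
  # empty input
  expect_equal(nrow(dedupe_reads(sam_records())), 0)
})

test_that("supplementary lines follow their primary's fate through dedup", {
  c1 <- chim_pair("x", c(100, 130), c(400, 425))
  c2 <- chim_pair("y", c(100, 130), c(400, 425)) # duplicate of x
  dd <- dedupe_reads(bind_sam(c1, c2))
  expect_equal(nrow(dd), 2) # x's primary + supplementary only
  expect_setequal(dd$qname, "x")
})

test_that("chimera arms come from the primary and SA alignment intervals", {
  cs <- extract_chimeras(chim_pair("r1", c(100, 130), c(400, 425)))
  expect_equal(nrow(cs$chimeras), 1)
  expect_equal(unlist(cs$chimeras[1, c("arm1_start", "arm1_end",
                                       "arm2_start", "arm2_end")],
                      use.names = FALSE),
               c(100, 130, 400, 425))
  expect_equal(cs$total_mapped, 1) # only the primary counts
})

test_that("non-chimeric primaries count toward total_mapped only", {
  recs <- bind_sam(chim_pair("c", c(100, 130), c(400, 425)),
                   linear_read("l1", 50L), linear_read("l2", 200L))
  cs <- extract_chimeras(recs)
  expect_equal(nrow(cs$chimeras), 1)
  expect_equal(cs$total_mapped, 3)
})

test_that("multi-SA (3-arm) chimeras are discarded and counted", {
  r <- chim_pair("m", c(100, 130), c(400, 425))
  r$sa[1] <- paste0(r$sa[1], "precursor,10,+,10M,60,0;")
  cs <- extract_chimeras(r)
  expect_equal(nrow(cs$chimeras), 0)
  expect_equal(cs$n_multi_sa, 1L)
})

test_that("minus-strand primaries are excluded from chimeras but mapped", {
  r <- chim_pair("m", c(100, 130), c(400, 425), flag1 = 16L)
  cs <- extract_chimeras(r)
  expect_equal(nrow(cs$chimeras), 0)
  expect_equal(cs$n_minus_strand, 1L)
  expect_equal(cs$total_mapped, 1)
})

test_that("chimera mapq is the minimum of the two arms", {
  r <- chim_pair("r", c(100, 130), c(400, 425), mapq = 60L)
  r$sa[1] <- "precursor,401,+,30S25M,13,0;"
  cs <- extract_chimeras(r)
  expect_equal(cs$chimeras$mapq, 13)
})

test_that("mapq and arm-span filters use strict inequalities", {
  lay <- big_layout()
  mk <- function(mapq, len) {
    data.frame(read_id = "x", arm1_start = 0L, arm1_end = 0L + len,
               arm2_start = 100L, arm2_end = 100L + len, mapq = mapq)
  }
  expect_equal(nrow(filter_chimeras(mk(20, 25), lay)), 0) # mapq 20 rejected
  expect_equal(nrow(filter_chimeras(mk(21, 25), lay)), 1) # 21 retained
  expect_equal(nrow(filter_chimeras(mk(60, 10), lay)), 0) # arm length 10 rejected
  expect_equal(nrow(filter_chimeras(mk(60, 11), lay)), 1) # 11 retained
})

test_that("arm pairs consistent with the ligated E1-E2 junction are removed", {
  lay <- big_layout()
  e1e <- lay$e1_interval[2]; e2s <- lay$e2_interval[1]
  junctionish <- data.frame(read_id = "j", arm1_start = e2s,
                            arm1_end = e2s + 20L, arm2_start = e1e - 20L,
                            arm2_end = e1e, mapq = 60L)
  expect_equal(nrow(filter_chimeras(junctionish, lay)), 0)
  # 6 nt away from the junction (tolerance 5) is kept
  shifted <- junctionish
  shifted$arm1_start <- e2s + 6L
  shifted$arm2_end <- e1e - 6L
  expect_equal(nrow(filter_chimeras(shifted, lay)), 1)
})

test_that("window binning floors arm starts and drops singletons", {
  chim <- data.frame(read_id = c("a", "b", "c"),
                     arm1_start = c(103L, 104L, 250L), arm1_end = c(128L, 129L, 275L),
                     arm2_start = c(411L, 412L, 330L), arm2_end = c(436L, 437L, 355L),
                     mapq = 60L)
  map <- bin_and_normalize(chim, window_size = 10, total_mapped = 1000)
  # (103, 411) and (104, 412) both bin to (10, 41); (250, 330) is a singleton
  expect_equal(nrow(map$counts), 1)
  expect_equal(map$counts$win_i, 10)
  expect_equal(map$counts$win_j, 41)
  expect_equal(map$counts$count, 2)
  expect_equal(map$counts$normalized, 2 / 1000)
  expect_error(bin_and_normalize(chim, total_mapped = 0), "total_mapped")
})

test_that("4 chimeras in one pair over 1000 mapped reads normalize to 0.004", {
  chim <- data.frame(read_id = letters[1:4], arm1_start = 103L,
                     arm1_end = 128L, arm2_start = 411L, arm2_end = 436L,
                     mapq = 60L)
  map <- bin_and_normalize(chim, window_size = 10, total_mapped = 1000)
  expect_equal(map$counts$normalized, 0.004)
})

test_that("interaction categories follow region labels with precedence", {
  # synthetic 60-nt reference: H1 | P2 | P9 | GOI | E1 | H2, 10 nt each
  regions <- rep(c("H1", "P2", "P9", "GOI", "E1", "H2"), each = 10)
  mk_map <- function(pairs, counts) {
    structure(list(window_size = 10,
                   counts = data.frame(win_i = pairs[, 1], win_j = pairs[, 2],
                                       count = counts,
                                       normalized = counts / 1000),
                   total_mapped = 1000),
              class = "interaction_map")
  }
  map <- mk_map(rbind(c(2, 2), c(1, 2), c(1, 3), c(3, 3), c(0, 2), c(2, 4)),
                c(4, 3, 2, 2, 5, 2))
  cl <- classify_interactions(map, regions)
  expect_equal(cl$pairs$category,
               c("intron-intron same-domain", "intron-intron cross-domain",
                 "intron-GOI", "GOI-GOI", "homology-involved", "other"))
  # aggregates partition the total normalized signal
  expect_equal(sum(cl$aggregates$normalized), sum(map$counts$normalized))
  expect_setequal(cl$aggregates$category,
                  c("homology-involved", "intron-intron same-domain",
                    "intron-intron cross-domain", "intron-GOI", "GOI-GOI",
                    "other"))
})

mk_map_kv <- function(keys, values) {
  ij <- do.call(rbind, strsplit(keys, ":"))
  structure(list(window_size = 10,
                 counts = data.frame(win_i = as.integer(ij[, 1]),
                                     win_j = as.integer(ij[, 2]),
                                     count = round(values * 1000),
                                     normalized = values),
                 total_mapped = 1000),
            class = "interaction_map")
}

test_that("differential testing matches the pooled-variance formula", {
  a <- c(0.004, 0.005); b <- c(0.001, 0.001)
  groupA <- lapply(a, function(v) mk_map_kv("1:5", v))
  groupB <- lapply(b, function(v) mk_map_kv("1:5", v))
  res <- differential_interactions(groupA, groupB)
  # closed-form pooled t on 2+2 values, written out
  sp2 <- (var(a) + var(b)) / 2
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  p_hand <- 2 * pt(-abs(t_hand), df = 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  # and against stats::t.test as independent oracle
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$meanA, mean(a))
  expect_equal(res$meanB, mean(b))
})

test_that("identical constant groups give p = 1; missing keys impute zero", {
  g <- lapply(c(0.002, 0.002), function(v) mk_map_kv("1:5", v))
  res <- differential_interactions(g, g)
  expect_equal(res$p, 1)
  expect_equal(res$t, 0)
  expect_false(res$significant)
  # key present only in group A: B replicates observed as zeros
  ga <- lapply(c(0.004, 0.006), function(v) mk_map_kv("1:5", v))
  gb <- lapply(c(0.001, 0.003), function(v) mk_map_kv("2:7", v))
  res2 <- differential_interactions(ga, gb)
  expect_equal(nrow(res2), 2)
  r15 <- res2[res2$win_i == 1, ]
  tt <- t.test(c(0.004, 0.006), c(0, 0), var.equal = TRUE)
  expect_equal(r15$p, tt$p.value, tolerance = 1e-10)
  expect_error(differential_interactions(ga[1], gb), "2 replicates")
})

test_that("pipeline output equals the brute-force enumeration on random fixtures", {
  lay <- big_layout()
  set.seed(31)
  for (i in 1:25) {
    recs <- random_sam_fixture(lay)
    dd <- dedupe_reads(recs)
    cs <- extract_chimeras(dd)
    fs <- filter_chimeras(cs, lay)
    map <- bin_and_normalize(fs)
    oracle <- brute_splash(recs, lay)
    expect_equal(map$total_mapped, oracle$total_mapped)
    expect_equal(sorted_counts(paste(map$counts$win_i, map$counts$win_j),
                               map$counts$count),
                 sorted_counts(names(oracle$counts),
                               unlist(oracle$counts) %||% integer(0)))
  }
})

test_that("normalization conserves counts and dedup never increases them", {
  lay <- big_layout()
  set.seed(32)
  recs <- random_sam_fixture(lay)
  dd <- dedupe_reads(recs)
  expect_lte(nrow(dd), nrow(recs))
  cs <- extract_chimeras(dd)
  fs <- filter_chimeras(cs, lay)
  map <- bin_and_normalize(fs)
  # window pairs in the map sum to the retained (non-singleton) chimeras
  if (nrow(map$counts)) {
    expect_equal(map$counts$normalized * map$total_mapped, map$counts$count)
    expect_true(all(map$counts$count >= 2))
  }
  expect_lte(sum(map$counts$count), nrow(fs$chimeras))
})
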