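# Event classification, motif maps, window tests, CLIP proximity.

test_that("events classify by junction dPSI thresholds", {
  tab <- data.frame(
    event = c("e1", "e1", "e2", "e2", "e3", "e3", "e4", "e5", "e5"),
    junction = c("j1", "j2", "j1", "j2", "j1", "j2", "j1", "j1", "j2"),
    dpsi_percent = c(15, -15, -12, 11, 2, -1, 7, -20, 18),
    role = c("inclusion", "exclusion", "inclusion", "exclusion",
             "inclusion", "exclusion", "inclusion", "inclusion", "exclusion"))
  es <- classify_events(tab)
  expect_equal(es$regulated_included, "e1")
  expect_equal(es$regulated_excluded, c("e2", "e5"))
  expect_equal(es$non_regulated, "e3")
  expect_equal(es$unassigned, "e4")
  # pairwise disjoint
  all_ids <- c(es$regulated_included, es$regulated_excluded,
               es$non_regulated, es$unassigned)
  expect_equal(anyDuplicated(all_ids), 0)

  bad <- tab; bad$role[1] <- "junk"
  expect_error(classify_events(bad), "malformed")
  oob <- tab; oob$dpsi_percent[1] <- 150
  expect_error(classify_events(oob), "-100")
})

test_that("motif frequency counts overlapping starts per position", {
  rs <- region_seq_set(c(e1 = "AAUG"), c(e1 = "UAAUU"), c(e1 = "CCCC"))
  mf <- motif_frequency(rs, c("AAU"))
  expect_equal(mf$upstream_intron$freq, c(1, 0))
  # UAAUU with all three motifs: starts at 1 (UAA), 2 (AAU), 3 (AUU)
  mf3 <- motif_frequency(rs, c("AAU", "UAA", "AUU"))
  expect_equal(mf3$exon$freq, c(1, 1, 1))
  expect_equal(mf3$downstream_intron$freq, c(0, 0))

  # two events, motif in one: frequency 0.5 where both covered
  rs2 <- region_seq_set(c(e1 = "AAUGG", e2 = "GGGGG"),
                        c(e1 = "CCC", e2 = "CCC"),
                        c(e1 = "CCC", e2 = "CCC"))
  f2 <- motif_frequency(rs2, c("AAU"))
  expect_equal(f2$upstream_intron$freq, c(0.5, 0, 0))
  expect_equal(f2$upstream_intron$coverage, c(2, 2, 2))

  # variable lengths: short sequences only contribute where they exist
  rs3 <- region_seq_set(c(e1 = "AAAAAA", e2 = "AAA"),
                        c(e1 = "CCC", e2 = "CCC"),
                        c(e1 = "CCC", e2 = "CCC"))
  f3 <- motif_frequency(rs3, c("AAA"))
  expect_equal(f3$upstream_intron$coverage, c(2, 1, 1, 1))
  expect_equal(f3$upstream_intron$freq, c(1, 1, 1, 1))

  expect_error(motif_frequency(rs, c("AXU")), "alphabet")
  # T in input maps to U
  rsT <- region_seq_set(c(e1 = "AAT"), c(e1 = "CCC"), c(e1 = "CCC"))
  expect_equal(motif_frequency(rsT, "AAU")$upstream_intron$freq, 1)
})

test_that("union frequency over motifs dominates any single motif", {
  sq <- synth_sequences(n_events_per_set = 40, seed = 5)
  all3 <- motif_frequency(sq$regulated, c("AAU", "UAA", "AUU"))
  one <- motif_frequency(sq$regulated, "AAU")
  expect_true(all(all3$downstream_intron$freq >= one$downstream_intron$freq))
})

test_that("running mean smooths with truncated boundary windows", {
  expect_equal(smooth_track(rep(3, 50), 20), rep(3, 50))
  x <- c(rep(0, 30), 1, rep(0, 30))
  sm <- smooth_track(x, 20)
  expect_equal(max(sm), 1 / 20)
  expect_equal(sum(sm > 0), 20)
  # each value equals the direct mean of its (truncated) window
  set.seed(6)
  y <- stats::runif(40)
  sm2 <- smooth_track(y, 7)
  for (i in c(1, 2, 20, 39, 40)) {
    lo <- max(1, i - 3); hi <- min(40, i + 3)
    expect_equal(sm2[i], mean(y[lo:hi]))
  }
  expect_equal(smooth_track(y, 100), rep(mean(y), 40))
  expect_error(smooth_track(y, 0), "width")
})

test_that("window Fisher matches the exact 2x2 computation and is symmetric", {
  expect_equal(eigrad:::fisher_p(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    tb <- matrix(sample(0:12, 4, replace = TRUE), 2)
    expect_equal(eigrad:::fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 fisher_two_sided_exact(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    # swapping the two sets leaves the two-tailed p unchanged
    expect_equal(eigrad:::fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 eigrad:::fisher_p(tb[3], tb[4], tb[1], tb[2]),
                 tolerance = 1e-12)
  }
})

test_that("identical event sets yield p = 1 everywhere", {
  sq <- synth_sequences(n_events_per_set = 30, seed = 9)
  wf <- window_fisher(sq$control, sq$control)
  expect_true(all(abs(wf$downstream_intron$p - 1) < 1e-7))
  expect_false(any(wf$downstream_intron$significant))
})

test_that("planted enrichment produces significant windows only near the plant", {
  sq <- synth_sequences(n_events_per_set = 200, planted_rate = 0.5,
                        planted_window = c(180, 220), seed = 12)
  wf <- window_fisher(sq$regulated, sq$control)
  dn <- wf$downstream_intron
  sig <- dn[dn$significant, ]
  expect_gt(nrow(sig), 0)
  # windows overlapping the planted span must be called
  span <- sig$window_start + 19 >= 180 & sig$window_start <= 220
  expect_true(any(span))
  # the planted span dominates: strongest window lies in/near it
  best <- dn$window_start[which.max(dn$minus_log10_p)]
  expect_gte(best + 19, 170)
  expect_lte(best, 230)
  # null regions stay near the nominal false-positive rate
  up <- wf$upstream_intron
  expect_lte(mean(up$significant), 0.10)
})

test_that("region FASTA round-trips with structured headers", {
  sq <- synth_sequences(n_events_per_set = 5, seed = 3)
  f <- tempfile(fileext = ".fa")
  write_region_fasta(sq$regulated, f)
  back <- read_region_fasta(f)
  expect_identical(back$regions, sq$regulated$regions)
  expect_identical(back$events, sq$regulated$events)
  unlink(f)
})

test_that("clip proximity filters weak tags and respects half-open windows", {
  events <- data.frame(event = c("e1", "e2"), chrom = c("e1", "e2"),
                       exon_start = 300, exon_end = 450,
                       set = c("reg", "ctl"))
  tags <- data.frame(chrom = c("e1", "e1", "e2"),
                     start = c(100, 300, 200), end = c(101, 301, 201),
                     tag_count = c(2, 2, 1))
  cp <- clip_proximity(tags, events, up = 300, down = 300, min_tags = 2)
  b <- cp$bound
  expect_true(b$upstream[b$event == "e1"])   # site 100 in [0, 300)
  expect_true(b$exon[b$event == "e1"])       # site 300 at exon start (incl.)
  expect_false(b$any[b$event == "e2"])       # single-tag site filtered
  expect_equal(unname(cp$fractions["reg", "any"]), 1)
  expect_equal(unname(cp$fractions["ctl", "any"]), 0)

  bad <- tags; bad$end[1] <- bad$start[1]
  expect_error(clip_proximity(bad, events), "half-open")
})

test_that("clip pairwise Fisher matches the exact table computation", {
  events <- data.frame(event = paste0("e", 1:200),
                       chrom = paste0("e", 1:200),
                       exon_start = 300, exon_end = 450,
                       set = rep(c("reg", "ctl"), each = 100))
  # 30/100 bound in reg, 10/100 in ctl
  bound_ids <- c(paste0("e", 1:30), paste0("e", 101:110))
  tags <- data.frame(chrom = bound_ids, start = 350, end = 351,
                     tag_count = 3)
  cp <- clip_proximity(tags, events)
  expect_equal(cp$fisher$p, fisher_two_sided_exact(30, 70, 10, 90),
               tolerance = 1e-12)
})

test_that("synthetic tags land at planted motifs and enrich the regulated arm", {
  sq <- synth_sequences(n_events_per_set = 150, planted_rate = 0.5,
                        tag_rate = 0.8, seed = 21)
  cp <- clip_proximity(sq$tags, sq$events)
  expect_gt(cp$fractions["regulated", "downstream"],
            cp$fractions["control", "downstream"])
  expect_lt(cp$fisher$p[1], 0.01)
})
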