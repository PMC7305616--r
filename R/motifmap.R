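# Positional motif maps around cassette exons and CLIP-tag proximity.
#
# Events are cassette (skipped) exons. Three anchored regions per event:
# the end of the upstream intron (anchored at the exon's 3' splice site),
# the cassette exon itself (5'->3'), and the start of the downstream intron
# (anchored at the exon's 5' splice site). Sequences are RNA (T mapped to U
# on read), already strand-resolved.

REGION_NAMES <- c("upstream_intron", "exon", "downstream_intron")

#' Construct an anchored region sequence set
#'
#' @param upstream,exon,downstream named character vectors (one sequence per
#'   event, names = event IDs, consistent across regions). Sequences are
#'   uppercased and T is mapped to U.
#' @return object of class `region_seq_set`.
#' @export
region_seq_set <- function(upstream, exon, downstream) {
  evs <- names(upstream)
  if (is.null(evs) || !identical(evs, names(exon)) ||
      !identical(evs, names(downstream)))
    stop("regions must share identical event names")
  norm <- function(s) chartr("Tt", "Uu", toupper(s))
  structure(list(regions = list(upstream_intron = norm(upstream),
                                exon = norm(exon),
                                downstream_intron = norm(downstream)),
                 events = evs),
            class = "region_seq_set")
}

#' @export
print.region_seq_set <- function(x, ...) {
  cat("Region sequence set: ", length(x$events), " events; region lengths ",
      paste(vapply(x$regions, function(r) max(nchar(r)), 1), collapse = "/"),
      " (up/exon/down)\n", sep = "")
  invisible(x)
}

#' Write / read anchored region sequences as FASTA
#'
#' Headers follow `eventID|region|length`. Reading accepts DNA or RNA
#' alphabets (T is mapped to U).
#' @param rset a `region_seq_set`.
#' @param file FASTA path.
#' @export
write_region_fasta <- function(rset, file) {
  seqs <- unlist(lapply(REGION_NAMES, function(rn) {
    s <- rset$regions[[rn]]
    stats::setNames(s, paste(names(s), rn, nchar(s), sep = "|"))
  }))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), file)
  invisible(file)
}

#' @rdname write_region_fasta
#' @export
read_region_fasta <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  seqs <- as.character(ss)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  ev <- vapply(parts, `[`, "", 1)
  rn <- vapply(parts, `[`, "", 2)
  if (!all(rn %in% REGION_NAMES))
    stop("unknown region labels in FASTA headers")
  get <- function(r) {
    sel <- rn == r
    stats::setNames(seqs[sel], ev[sel])[unique(ev)]
  }
  region_seq_set(get("upstream_intron"), get("exon"),
                 get("downstream_intron"))
}

#' Classify events by junction delta-PSI
#'
#' Regulated events have both an inclusion and an exclusion junction with
#' |dPSI| at or above `reg_threshold` (percent) and are split by the sign of
#' the inclusion junction; non-regulated events have all junctions below
#' `nonreg_threshold`; events between the thresholds stay unassigned.
#'
#' @param dpsi_table data.frame with columns `event`, `junction`,
#'   `dpsi_percent` (in \[-100, 100\]) and `role` ("inclusion"/"exclusion").
#' @param reg_threshold regulated threshold in percent (default 10).
#' @param nonreg_threshold non-regulated threshold in percent (default 5).
#' @return object of class `event_sets` with disjoint ID vectors
#'   `regulated_included`, `regulated_excluded`, `non_regulated`,
#'   `unassigned`.
#' @export
classify_events <- function(dpsi_table, reg_threshold = 10,
                            nonreg_threshold = 5) {
  need <- c("event", "junction", "dpsi_percent", "role")
  if (!all(need %in% names(dpsi_table)))
    stop("dpsi_table must have columns: ", paste(need, collapse = ", "))
  if (!all(dpsi_table$role %in% c("inclusion", "exclusion")))
    stop("malformed junction roles (expected inclusion/exclusion)")
  if (any(abs(dpsi_table$dpsi_percent) > 100))
    stop("dpsi_percent outside [-100, 100]")
  inc_set <- exc_set <- non <- un <- character(0)
  for (ev in unique(dpsi_table$event)) {
    d <- dpsi_table[dpsi_table$event == ev, ]
    inc <- d[d$role == "inclusion", ]
    exc <- d[d$role == "exclusion", ]
    big_inc <- abs(inc$dpsi_percent) >= reg_threshold
    big_exc <- abs(exc$dpsi_percent) >= reg_threshold
    if (any(big_inc) && any(big_exc)) {
      # direction from the strongest inclusion junction
      lead <- inc$dpsi_percent[which.max(abs(inc$dpsi_percent))]
      if (lead > 0) inc_set <- c(inc_set, ev) else exc_set <- c(exc_set, ev)
    } else if (all(abs(d$dpsi_percent) < nonreg_threshold)) {
      non <- c(non, ev)
    } else {
      un <- c(un, ev)
    }
  }
  structure(list(regulated_included = inc_set, regulated_excluded = exc_set,
                 non_regulated = non, unassigned = un,
                 thresholds = c(regulated = reg_threshold,
                                non_regulated = nonreg_threshold)),
            class = "event_sets")
}

#' @export
print.event_sets <- function(x, ...) {
  cat("Event sets: ", length(x$regulated_included), " included / ",
      length(x$regulated_excluded), " excluded / ",
      length(x$non_regulated), " non-regulated / ",
      length(x$unassigned), " unassigned\n", sep = "")
  invisible(x)
}

# per-event motif start positions within one sequence (overlaps allowed)
motif_starts <- function(seq, motifs) {
  hits <- integer(0)
  for (m in motifs) {
    mv <- Biostrings::matchPattern(m, Biostrings::BString(seq))
    hits <- c(hits, Biostrings::start(mv))
  }
  sort(unique(hits))
}

#' Per-position motif occurrence frequency
#'
#' For each anchored region, position i counts an occurrence for an event
#' when any motif starts at i; the frequency divides by the number of events
#' whose sequence is long enough to host a motif start at i.
#'
#' @param rset a `region_seq_set`.
#' @param motifs character vector of RNA motifs (e.g. `c("AAU","UAA","AUU")`).
#' @return list of class `motif_track`, one element per region with
#'   `freq`, `coverage` and `positions`.
#' @export
motif_frequency <- function(rset, motifs = c("AAU", "UAA", "AUU")) {
  if (length(rset$events) == 0) stop("empty region set")
  motifs <- chartr("Tt", "Uu", toupper(motifs))
  if (!all(strsplit(paste(motifs, collapse = ""), "")[[1]] %in%
           c("A", "C", "G", "U")))
    stop("motifs must be over the RNA alphabet {A,C,G,U}")
  mlen <- min(nchar(motifs))
  out <- lapply(rset$regions, function(seqs) {
    L <- max(nchar(seqs))
    npos <- L - mlen + 1
    cnt <- numeric(npos)
    cov <- numeric(npos)
    for (s in seqs) {
      ns <- nchar(s) - mlen + 1
      if (ns < 1) next
      cov[seq_len(ns)] <- cov[seq_len(ns)] + 1
      st <- motif_starts(s, motifs)
      cnt[st] <- cnt[st] + 1
    }
    freq <- ifelse(cov > 0, cnt / cov, NA_real_)
    list(freq = freq, coverage = cov, positions = seq_len(npos))
  })
  structure(out, class = "motif_track", motifs = motifs)
}

#' Running-mean smoothing of a positional track
#'
#' Centred running mean of `width` positions with truncated windows at the
#' track boundaries (no padding). A width exceeding the track length yields
#' the global mean everywhere.
#'
#' @param x numeric track.
#' @param width window width in nucleotides (default 20).
#' @export
smooth_track <- function(x, width = 20) {
  if (width < 1) stop("width must be >= 1")
  n <- length(x)
  if (width >= n) return(rep(mean(x), n))
  half_lo <- floor((width - 1) / 2)
  half_hi <- width - 1 - half_lo
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}

# two-tailed Fisher p for a 2x2 table, as stats::fisher.test
fisher_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
}

#' Sliding-window Fisher test of motif occurrence between event sets
#'
#' At each window start (stride 1 nt), counts the events in each set that
#' contain at least one motif starting within the 20-nt window and tests the
#' resulting 2x2 presence table with a two-tailed Fisher's exact test.
#' Events whose sequence does not cover the full window are excluded from
#' that window's table.
#'
#' @param setA,setB `region_seq_set` objects (e.g. regulated vs
#'   non-regulated events).
#' @param motifs character vector of RNA motifs.
#' @param window window width in nucleotides (default 20).
#' @param alpha significance level for the mask (default 0.05; no
#'   multiple-testing correction across windows, by design).
#' @return list per region: data.frame with `window_start`, `center`,
#'   `present_A`, `n_A`, `present_B`, `n_B`, `p`, `minus_log10_p`,
#'   `significant`. Regions shorter than the window yield empty frames.
#' @export
window_fisher <- function(setA, setB, motifs = c("AAU", "UAA", "AUU"),
                          window = 20, alpha = 0.05) {
  if (length(setA$events) == 0 || length(setB$events) == 0)
    stop("both event sets must be non-empty")
  motifs <- chartr("Tt", "Uu", toupper(motifs))
  out <- lapply(REGION_NAMES, function(rn) {
    sa <- setA$regions[[rn]]
    sb <- setB$regions[[rn]]
    L <- max(c(nchar(sa), nchar(sb)))
    if (window > L)
      return(data.frame(window_start = integer(0), center = integer(0),
                        present_A = integer(0), n_A = integer(0),
                        present_B = integer(0), n_B = integer(0),
                        p = numeric(0), minus_log10_p = numeric(0),
                        significant = logical(0)))
    starts_a <- lapply(sa, motif_starts, motifs = motifs)
    starts_b <- lapply(sb, motif_starts, motifs = motifs)
    ws <- seq_len(L - window + 1)
    res <- t(vapply(ws, function(w) {
      hi <- w + window - 1
      cov_a <- nchar(sa) >= hi
      cov_b <- nchar(sb) >= hi
      pa <- vapply(starts_a[cov_a],
                   function(st) any(st >= w & st <= hi), logical(1))
      pb <- vapply(starts_b[cov_b],
                   function(st) any(st >= w & st <= hi), logical(1))
      nA <- sum(cov_a); nB <- sum(cov_b)
      p <- if (nA == 0 || nB == 0) 1 else
        fisher_p(sum(pa), nA - sum(pa), sum(pb), nB - sum(pb))
      c(sum(pa), nA, sum(pb), nB, p)
    }, numeric(5)))
    data.frame(window_start = ws, center = ws + floor(window / 2),
               present_A = res[, 1], n_A = res[, 2],
               present_B = res[, 3], n_B = res[, 4],
               p = res[, 5], minus_log10_p = -log10(res[, 5]),
               significant = res[, 5] < alpha)
  })
  names(out) <- REGION_NAMES
  out
}

#' Write per-region motif tracks and window tests as TSV
#' @param freqA,freqB `motif_track` objects for the two sets.
#' @param wf result of [window_fisher()].
#' @param dir output directory (one TSV per region).
#' @param width smoothing width passed to [smooth_track()].
#' @export
write_motif_tracks <- function(freqA, freqB, wf, dir, width = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rn in REGION_NAMES) {
    fa <- freqA[[rn]]$freq
    fb <- freqB[[rn]]$freq
    n <- min(length(fa), length(fb))
    df <- data.frame(position = seq_len(n),
                     freq_A = fa[seq_len(n)], freq_B = fb[seq_len(n)],
                     smoothed_A = smooth_track(fa[seq_len(n)], width),
                     smoothed_B = smooth_track(fb[seq_len(n)], width))
    w <- wf[[rn]]
    df$fisher_p <- df$minus_log10_p <- NA_real_
    df$significant <- NA
    if (nrow(w) > 0) {
      df$fisher_p[w$center[w$center <= n]] <- w$p[w$center <= n]
      df$minus_log10_p[w$center[w$center <= n]] <-
        w$minus_log10_p[w$center <= n]
      df$significant[w$center[w$center <= n]] <- w$significant[w$center <= n]
    }
    utils::write.table(df, file.path(dir, paste0(rn, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' CLIP-tag proximity enrichment around cassette exons
#'
#' Retains crosslink transition sites supported by at least `min_tags`
#' unique tags and calls an event "bound" when a retained site falls in the
#' upstream window, the cassette exon, or the downstream window (each region
#' is also reported separately). Bound fractions are compared between event
#' sets with two-tailed Fisher's exact tests. Coordinates are 0-based,
#' half-open.
#'
#' @param tags data.frame with `chrom`, `start`, `end`, `tag_count`
#'   (single-nucleotide transition sites, `end = start + 1`).
#' @param events data.frame with `event`, `chrom`, `exon_start`, `exon_end`,
#'   `set` (the event-set label).
#' @param up,down window sizes in nucleotides (default 300).
#' @param min_tags minimum unique-tag support (default 2).
#' @return list with `bound` (per event/region logical data.frame),
#'   `fractions` (per set x region), `fisher` (pairwise set comparisons on
#'   the any-region bound counts).
#' @export
clip_proximity <- function(tags, events, up = 300, down = 300, min_tags = 2) {
  if (any(tags$end <= tags$start) ||
      any(events$exon_end <= events$exon_start))
    stop("invalid intervals: end must exceed start (0-based half-open)")
  keep <- tags$tag_count >= min_tags
  tg <- tags[keep, , drop = FALSE]
  hit <- function(chrom, lo, hi) {
    any(tg$chrom == chrom & tg$start >= lo & tg$start < hi)
  }
  bound <- data.frame(event = events$event, set = events$set,
                      upstream = FALSE, exon = FALSE, downstream = FALSE)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    bound$upstream[i] <- hit(e$chrom, e$exon_start - up, e$exon_start)
    bound$exon[i] <- hit(e$chrom, e$exon_start, e$exon_end)
    bound$downstream[i] <- hit(e$chrom, e$exon_end, e$exon_end + down)
  }
  bound$any <- bound$upstream | bound$exon | bound$downstream
  sets <- unique(bound$set)
  fractions <- t(vapply(sets, function(s) {
    b <- bound[bound$set == s, ]
    c(upstream = mean(b$upstream), exon = mean(b$exon),
      downstream = mean(b$downstream), any = mean(b$any))
  }, numeric(4)))
  rownames(fractions) <- sets
  pairs <- if (length(sets) >= 2) utils::combn(sets, 2, simplify = FALSE)
           else list()
  fisher <- do.call(rbind, lapply(pairs, function(pr) {
    a <- bound$any[bound$set == pr[1]]
    b <- bound$any[bound$set == pr[2]]
    data.frame(set_a = pr[1], set_b = pr[2],
               bound_a = sum(a), n_a = length(a),
               bound_b = sum(b), n_b = length(b),
               p = fisher_p(sum(a), length(a) - sum(a),
                            sum(b), length(b) - sum(b)))
  }))
  list(bound = bound, fractions = fractions, fisher = fisher,
       min_tags = min_tags, up = up, down = down)
}
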