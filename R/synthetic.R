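# Seeded synthetic generators.
#
# Three generators mirror the three data shapes the framework consumes:
# class-structured tabular data with correlated feature blocks and planted
# discriminative features; digit-like binary images with class-specific
# stroke patterns; and splice-region sequence sets with 3-mers planted in a
# positional window plus matching synthetic crosslink tags. Every generator
# records its ground truth so precision/recall of downstream calls can be
# scored without external references.

#' Synthetic two-class tabular data with correlated feature blocks
#'
#' Features are built from shared latent block factors,
#' `x = noise_sd * (sqrt(block_r) f_block + sqrt(1 - block_r) eps)`, giving a
#' within-block correlation of `block_r` and guaranteed positive-definite
#' structure at any p. Informative features (one per block while blocks
#' last) are shifted by `effect_size * noise_sd` in class B.
#'
#' @param n number of samples (split evenly between classes A and B).
#' @param p number of features.
#' @param n_informative number of planted discriminative features.
#' @param effect_size between-class shift in units of `noise_sd`.
#' @param block_size features per correlated block.
#' @param block_r target within-block correlation in \[0, 1).
#' @param noise_sd feature scale.
#' @param seed integer seed; output is bit-reproducible.
#' @return list of class `synth_tabular`: `features` (n x p, named columns),
#'   `labels` ("A"/"B"), `truth` (informative feature names, effect size,
#'   block membership vector).
#' @export
synth_tabular <- function(n = 400, p = 200, n_informative = 10,
                          effect_size = 3, block_size = 4, block_r = 0.6,
                          noise_sd = 1, seed = 1) {
  if (n_informative > p) stop("n_informative must not exceed p")
  if (block_r < 0 || block_r >= 1) stop("block_r must be in [0, 1)")
  set.seed(seed)
  n_blocks <- ceiling(p / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(p)]
  Fb <- matrix(stats::rnorm(n * n_blocks), n)
  E <- matrix(stats::rnorm(n * p), n)
  X <- noise_sd * (sqrt(block_r) * Fb[, block_of, drop = FALSE] +
                   sqrt(1 - block_r) * E)
  labels <- rep(c("A", "B"), length.out = n)
  # informative features spread over distinct blocks first
  by_depth <- order(stats::ave(seq_len(p), block_of, FUN = seq_along),
                    block_of)
  info_idx <- by_depth[seq_len(n_informative)]
  X[labels == "B", info_idx] <- X[labels == "B", info_idx] +
    effect_size * noise_sd
  colnames(X) <- paste0("f", seq_len(p))
  structure(list(features = X, labels = labels,
                 truth = list(informative = colnames(X)[info_idx],
                              effect_size = effect_size,
                              block = stats::setNames(block_of, colnames(X)),
                              block_r = block_r),
                 seed = seed),
            class = "synth_tabular")
}

#' Synthetic digit-like binary images
#'
#' Each class renders a fixed stroke pattern on an h x w canvas; pixels are
#' then flipped independently with probability `pixel_noise` (Bernoulli flip
#' noise keeps values in \{0, 1\} and makes the truth mask exact). The truth
#' mask marks pixels whose expected value differs between the two classes:
#' the symmetric difference of the patterns.
#'
#' @param n_per_class images per class.
#' @param h,w canvas size.
#' @param pattern_spec optional list of two logical h x w matrices (classes
#'   "A" and "B"); defaults to a vertical and a horizontal stroke.
#' @param pixel_noise flip probability in \[0, 0.5).
#' @param seed integer seed.
#' @return list of class `synth_images`: `images` (2n x h*w matrix, columns
#'   `px<r>_<c>`), `labels`, `truth` (`mask` = informative pixel names,
#'   `patterns`).
#' @export
synth_images <- function(n_per_class = 300, h = 16, w = 16,
                         pattern_spec = NULL, pixel_noise = 0.05, seed = 1) {
  if (pixel_noise < 0 || pixel_noise >= 0.5)
    stop("pixel_noise must be in [0, 0.5)")
  if (is.null(pattern_spec)) {
    A <- matrix(FALSE, h, w); A[3:(h - 2), floor(w / 3)] <- TRUE
    B <- matrix(FALSE, h, w); B[floor(h / 3), 3:(w - 2)] <- TRUE
    pattern_spec <- list(A = A, B = B)
  }
  stopifnot(length(pattern_spec) == 2,
            all(vapply(pattern_spec, function(m) all(dim(m) == c(h, w)),
                       logical(1))))
  if (identical(pattern_spec[[1]], pattern_spec[[2]]))
    warning("identical class patterns: classes are indistinguishable")
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("A", "B"), each = n_per_class)
  base <- rbind(
    matrix(rep(as.numeric(pattern_spec[[1]]), n_per_class), n_per_class,
           byrow = TRUE),
    matrix(rep(as.numeric(pattern_spec[[2]]), n_per_class), n_per_class,
           byrow = TRUE))
  flips <- matrix(stats::rbinom(n * h * w, 1, pixel_noise), n)
  imgs <- abs(base - flips)
  px <- expand.grid(r = seq_len(h), c = seq_len(w))
  colnames(imgs) <- paste0("px", px$r, "_", px$c)
  mask <- xor(as.logical(pattern_spec[[1]]), as.logical(pattern_spec[[2]]))
  structure(list(images = imgs, labels = labels, h = h, w = w,
                 truth = list(mask = colnames(imgs)[mask],
                              patterns = pattern_spec),
                 seed = seed),
            class = "synth_images")
}

#' Synthetic splice-region sequences with planted motif enrichment
#'
#' Generates two anchored region sets (a "regulated" arm and a background
#' "control" arm) with i.i.d. background nucleotides. In the regulated arm,
#' each event independently receives one planted motif at a uniform position
#' inside `planted_window` of the chosen region with probability
#' `planted_rate`. Synthetic crosslink tags (unique-tag count >= 2) are
#' emitted at planted motif positions with probability `tag_rate`;
#' low-support noise tags (count 1) are scattered over both arms.
#'
#' @param n_events_per_set events per arm.
#' @param region_lengths named vector: `upstream`, `exon`, `downstream`.
#' @param background_probs length-4 probabilities for A, C, G, U.
#' @param planted_motifs motifs to plant (one chosen per planted event).
#' @param planted_window c(lo, hi) positions within the planted region.
#' @param planted_region region receiving the plant.
#' @param planted_rate per-event planting probability.
#' @param tag_rate probability a planted motif emits a crosslink tag.
#' @param seed integer seed.
#' @return list of class `synth_sequences`: `regulated` and `control`
#'   (`region_seq_set`s), `tags`, `events` (coordinate table for
#'   [clip_proximity()]), `truth`.
#' @export
synth_sequences <- function(n_events_per_set = 200,
                            region_lengths = c(upstream = 300, exon = 150,
                                               downstream = 300),
                            background_probs = rep(0.25, 4),
                            planted_motifs = c("AAU", "UAA", "AUU"),
                            planted_window = c(180, 220),
                            planted_region = "downstream_intron",
                            planted_rate = 0.5, tag_rate = 0.8, seed = 1) {
  if (planted_rate < 0 || planted_rate > 1)
    stop("planted_rate must be in [0, 1]")
  mlen <- max(nchar(planted_motifs))
  reg_len <- switch(planted_region,
                    upstream_intron = region_lengths[["upstream"]],
                    exon = region_lengths[["exon"]],
                    downstream_intron = region_lengths[["downstream"]])
  if (planted_window[2] + mlen - 1 > reg_len || planted_window[1] < 1)
    stop("planted window does not fit the region (motif too long?)")
  set.seed(seed)
  alphabet <- c("A", "C", "G", "U")
  rand_seq <- function(len) {
    paste(sample(alphabet, len, replace = TRUE, prob = background_probs),
          collapse = "")
  }
  make_set <- function(prefix) {
    evs <- paste0(prefix, seq_len(n_events_per_set))
    up <- stats::setNames(vapply(evs, function(e)
      rand_seq(region_lengths[["upstream"]]), ""), evs)
    ex <- stats::setNames(vapply(evs, function(e)
      rand_seq(region_lengths[["exon"]]), ""), evs)
    dn <- stats::setNames(vapply(evs, function(e)
      rand_seq(region_lengths[["downstream"]]), ""), evs)
    region_seq_set(up, ex, dn)
  }
  regulated <- make_set("reg_")
  control <- make_set("ctl_")
  planted <- data.frame(event = character(0), pos = integer(0),
                        motif = character(0))
  for (ev in regulated$events) {
    if (stats::runif(1) < planted_rate) {
      pos <- sample(planted_window[1]:planted_window[2], 1)
      m <- sample(planted_motifs, 1)
      s <- regulated$regions[[planted_region]][[ev]]
      substr(s, pos, pos + nchar(m) - 1) <- m
      regulated$regions[[planted_region]][[ev]] <- s
      planted <- rbind(planted,
                       data.frame(event = ev, pos = pos, motif = m))
    }
  }
  # coordinates: each event on its own contig; 0-based half-open
  Lu <- region_lengths[["upstream"]]
  Le <- region_lengths[["exon"]]
  events <- data.frame(
    event = c(regulated$events, control$events),
    chrom = c(regulated$events, control$events),
    exon_start = Lu, exon_end = Lu + Le,
    set = rep(c("regulated", "control"),
              times = c(length(regulated$events), length(control$events))))
  region_offset <- switch(planted_region, upstream_intron = 0,
                          exon = Lu, downstream_intron = Lu + Le)
  tag_rows <- list()
  for (i in seq_len(nrow(planted))) {
    if (stats::runif(1) < tag_rate) {
      pos0 <- region_offset + planted$pos[i] - 1
      tag_rows[[length(tag_rows) + 1]] <-
        data.frame(chrom = planted$event[i], start = pos0, end = pos0 + 1,
                   tag_count = sample(2:4, 1))
    }
  }
  # low-support noise tags on both arms (filtered out at min_tags = 2)
  total_len <- sum(region_lengths)
  for (ev in sample(events$event, ceiling(nrow(events) / 4))) {
    pos0 <- sample.int(total_len, 1) - 1
    tag_rows[[length(tag_rows) + 1]] <-
      data.frame(chrom = ev, start = pos0, end = pos0 + 1, tag_count = 1L)
  }
  tags <- do.call(rbind, tag_rows)
  if (is.null(tags))
    tags <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), tag_count = integer(0))
  structure(list(regulated = regulated, control = control, tags = tags,
                 events = events,
                 truth = list(window = planted_window,
                              region = planted_region,
                              rate = planted_rate, motifs = planted_motifs,
                              planted = planted),
                 seed = seed),
            class = "synth_sequences")
}
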