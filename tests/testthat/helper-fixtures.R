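# Shared fixtures, all generated in code.

# Small desk-scale study config: ~60 drawings from 30 participants.
desk_config <- function(...) {
  study_config(n_participants = 30L, n_adults = 5L,
               media_weights = c(1, 1, 1), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small cohort + drawings table (ground truth included).
make_drawings <- function(seed = 1L, n_participants = 30L, config = NULL) {
  cfg <- config %||% desk_config()
  p <- sample_participants(n_participants, cfg, seed = seed)
  list(participants = p,
       drawings = derive_specs(p, config = cfg, seed = seed + 1L),
       config = cfg)
}

# Planted configuration drawn from the generator's perceptual manifold,
# truncated to exactly n drawings.
planted_manifold <- function(n = 60L, seed = 1L) {
  fx <- make_drawings(seed = seed, n_participants = ceiling(n / 2) + 5L)
  d <- fx$drawings[seq_len(min(n, nrow(fx$drawings))), ]
  x <- as.matrix(d[, c("perc_x", "perc_y")])
  rownames(x) <- d$drawing_id
  x
}

# Full-rank planted plane (uniform square). The generator's developmental
# arc is ordinally near-one-dimensional, so tests of planted
# *dimensionality* use this configuration instead.
planted_plane <- function(n = 50L, seed = 1L, half_width = 1.5) {
  set.seed(seed)
  x <- matrix(runif(2 * n, -half_width, half_width), n, 2)
  rownames(x) <- sprintf("d%03d", seq_len(n))
  x
}

# A tiny deterministic bitmap with an ink rectangle.
rect_bitmap <- function(nr, nc, rows, cols) {
  b <- matrix(FALSE, nr, nc)
  b[rows, cols] <- TRUE
  b
}

# Random small prepared bitmaps for feature/embedding tests.
make_bitmaps <- function(n = 8L, seed = 1L, side = 224L) {
  fx <- make_drawings(seed = seed, n_participants = n)
  d <- fx$drawings[seq_len(n), ]
  lapply(stats::setNames(seq_len(n), d$drawing_id), function(i)
    prep_image(render_drawing(d[i, ], side), side = side))
}
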