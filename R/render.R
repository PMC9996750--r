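# Procedural renderer for synthetic human-figure drawings.
#
# Drawings are composed from two primitives (line segments and circles)
# stamped with a square nib of the spec's stroke width onto a logical
# canvas (TRUE = ink). Geometry is laid out in unit coordinates (x right,
# y down) and mapped into a centered box of side figure_scale * canvas, so
# the ink bounding box never exceeds the configured figure scale.

stamp_points <- function(canvas, xs, ys, width) {
  side <- nrow(canvas)
  half <- max(0L, as.integer(floor(width / 2)))
  xs <- round(xs); ys <- round(ys)
  keep <- xs >= 1 & xs <= side & ys >= 1 & ys <= side
  xs <- xs[keep]; ys <- ys[keep]
  off <- seq(-half, half)
  for (dx in off) for (dy in off) {
    cx <- pmin(pmax(xs + dx, 1), side)
    cy <- pmin(pmax(ys + dy, 1), side)
    canvas[cbind(cy, cx)] <- TRUE
  }
  canvas
}

path_points <- function(x0, y0, x1, y1) {
  n <- max(2L, ceiling(2 * sqrt((x1 - x0)^2 + (y1 - y0)^2)))
  t <- seq(0, 1, length.out = n)
  list(x = x0 + t * (x1 - x0), y = y0 + t * (y1 - y0))
}

circle_points <- function(cx, cy, r) {
  n <- max(12L, ceiling(4 * pi * r))
  t <- seq(0, 2 * pi, length.out = n)
  list(x = cx + r * cos(t), y = cy + r * sin(t))
}

# Geometry of one figure in unit coordinates. Returns a list of elements,
# each list(kind = "seg"/"circle", coords...). Every present part
# contributes at least one element.
figure_geometry <- function(stage, parts, stroke_count, jitter) {
  el <- list()
  seg <- function(x0, y0, x1, y1)
    list(kind = "seg", x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  circ <- function(cx, cy, r) list(kind = "circle", cx = cx, cy = cy, r = r)
  j <- function(v) pmin(pmax(v + jitter(length(v)), 0.02), 0.98)

  if (stage == "scribble") {
    for (s in seq_len(stroke_count)) {
      pts <- cbind(j(stats::runif(5, 0.1, 0.9)), j(stats::runif(5, 0.1, 0.9)))
      for (i in seq_len(4))
        el[[length(el) + 1L]] <- seg(pts[i, 1], pts[i, 2],
                                     pts[i + 1, 1], pts[i + 1, 2])
    }
    return(el)
  }

  # head placement differs by stage
  head <- switch(stage,
                 circle_face = list(cx = 0.5, cy = 0.5, r = 0.33),
                 tadpole = list(cx = 0.5, cy = 0.32, r = 0.24),
                 differentiated = list(cx = 0.5, cy = 0.16, r = 0.13))
  hx <- j(head$cx); hy <- j(head$cy); hr <- head$r
  add <- function(part, ...) {
    if (isTRUE(parts[[part]]))
      for (e in list(...)) el[[length(el) + 1L]] <<- e
  }
  add("head", circ(hx, hy, hr))
  er <- hr * 0.16
  add("eyes", circ(hx - hr * 0.4, hy - hr * 0.25, er),
      circ(hx + hr * 0.4, hy - hr * 0.25, er))
  add("nose", seg(hx, hy - hr * 0.1, hx, hy + hr * 0.15))
  add("mouth", seg(hx - hr * 0.35, hy + hr * 0.45,
                   hx + hr * 0.35, hy + hr * 0.45))
  add("ears", circ(hx - hr * 1.08, hy, er * 1.3),
      circ(hx + hr * 1.08, hy, er * 1.3))
  if (isTRUE(parts[["hair"]]))
    for (a in seq(-1.1, 1.1, length.out = 5)) {
      bx <- hx + hr * sin(a) * 0.95; by <- hy - hr * cos(a) * 0.95
      el[[length(el) + 1L]] <- seg(bx, by, bx + 0.06 * sin(a),
                                   by - 0.07 * cos(a) - 0.02)
    }

  if (stage == "tadpole") {
    # limbs attach directly to the head
    ly0 <- hy + hr
    add("legs", seg(hx - hr * 0.45, ly0 - 0.02, j(0.38), 0.92),
        seg(hx + hr * 0.45, ly0 - 0.02, j(0.62), 0.92))
    add("arms", seg(hx - hr, hy + hr * 0.2, j(0.12), hy + 0.12),
        seg(hx + hr, hy + hr * 0.2, j(0.88), hy + 0.12))
    add("hands", circ(0.12, hy + 0.14, 0.04), circ(0.88, hy + 0.14, 0.04))
    add("feet", seg(0.38, 0.92, 0.32, 0.95), seg(0.62, 0.92, 0.68, 0.95))
  } else if (stage == "differentiated") {
    ty0 <- hy + hr                # top of trunk
    ty1 <- j(0.62)                # bottom of trunk
    add("body", seg(0.40, ty0, 0.40, ty1), seg(0.60, ty0, 0.60, ty1),
        seg(0.40, ty1, 0.60, ty1), seg(0.40, ty0, 0.60, ty0))
    ay <- ty0 + 0.05
    add("arms", seg(0.40, ay, j(0.15), ay + 0.12),
        seg(0.60, ay, j(0.85), ay + 0.12))
    add("hands", circ(0.15, ay + 0.14, 0.035), circ(0.85, ay + 0.14, 0.035))
    add("legs", seg(0.45, ty1, j(0.40), 0.93), seg(0.55, ty1, j(0.60), 0.93))
    add("feet", seg(0.40, 0.93, 0.33, 0.95), seg(0.60, 0.93, 0.67, 0.95))
    if (isTRUE(parts[["clothes"]]))
      for (yy in seq(ty0 + 0.06, ty1 - 0.04, length.out = 3))
        el[[length(el) + 1L]] <- seg(0.41, yy, 0.59, yy)
  }
  el
}

#' Render a synthetic human-figure drawing
#'
#' Rasterizes one drawing spec (a row of the table from
#' \code{\link{derive_specs}}) to a black-on-white binary bitmap.
#' Deterministic given the spec's \code{jitter_seed}; every checklist part
#' marked present contributes at least one visible stroke, and all ink lies
#' inside a centered box of side \code{figure_scale * canvas}.
#'
#' @param spec one-row data.frame (or list) with stage, part_* indicators,
#'   figure_scale, stroke_width, stroke_count, jitter_seed.
#' @param canvas output side length in pixels (>= 64).
#' @return logical matrix (canvas x canvas); TRUE = ink.
#' @export
render_drawing <- function(spec, canvas = 224L) {
  if (is.data.frame(spec)) {
    if (nrow(spec) != 1L) stopf("render_drawing takes a single spec row")
    spec <- as.list(spec)
  }
  canvas <- as.integer(canvas)
  if (canvas < 64L) stopf("canvas must be at least 64 pixels")
  width <- as.integer(spec$stroke_width %||% 2L)
  if (width >= canvas / 8) stopf("canvas too small for stroke width %d", width)
  stage <- as.character(spec$stage)
  if (stage == "scribble" && (spec$stroke_count %||% 0) < 1)
    stopf("empty drawing refused: scribble with no strokes")
  parts <- spec[paste0("part_", checklist_items())]
  names(parts) <- checklist_items()
  with_seed(spec$jitter_seed %||% 1L, {
    jitter <- function(n) stats::rnorm(n, 0, 0.015)
    el <- figure_geometry(stage, parts, spec$stroke_count %||% 4L, jitter)
    if (!length(el)) stopf("empty drawing refused: no strokes to render")
    box <- max(16L, as.integer(floor((spec$figure_scale %||% 0.8) * canvas)))
    off <- as.integer(floor((canvas - box) / 2))
    bmp <- matrix(FALSE, canvas, canvas)
    # map unit coords into the centered box, keeping the nib inside it
    half <- floor(width / 2)
    tr <- function(v) off + half + 1 +
      pmin(pmax(v, 0), 1) * (box - 2 * half - 2)
    for (e in el) {
      pts <- if (e$kind == "seg") path_points(e$x0, e$y0, e$x1, e$y1)
             else circle_points(e$cx, e$cy, e$r)
      bmp <- stamp_points(bmp, tr(pts$x), tr(pts$y), width)
    }
    bmp
  })
}

#' Render all drawings of a study
#'
#' @param drawings table from \code{\link{derive_specs}}.
#' @param canvas side length in pixels.
#' @return named list of logical bitmaps, one per drawing_id.
#' @export
render_all <- function(drawings, canvas = 224L) {
  out <- lapply(seq_len(nrow(drawings)),
                function(i) render_drawing(drawings[i, ], canvas))
  names(out) <- drawings$drawing_id
  out
}
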