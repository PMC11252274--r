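# Parametric stimulus image sets standing in for natural image stimuli:
# one shape + hue per class, with within-class-coherent luminance.

shape_mask <- function(kind, side, cx, cy, r) {
  x <- matrix(rep(seq_len(side), each = side), side) / side - cx
  y <- matrix(rep(seq_len(side), times = side), side) / side - cy
  d <- sqrt(x^2 + y^2)
  switch(kind,
    disc = d < r,
    ring = d < r & d > 0.55 * r,
    square = pmax(abs(x), abs(y)) < 0.85 * r,
    diamond = abs(x) + abs(y) < 1.1 * r,
    cross = (abs(x) < 0.3 * r & abs(y) < r) | (abs(y) < 0.3 * r & abs(x) < r),
    hbar = abs(y) < 0.4 * r & abs(x) < 1.2 * r,
    vbar = abs(x) < 0.4 * r & abs(y) < 1.2 * r,
    wedge = y > -r & y < 0.9 * r & abs(x) < (y + r) * 0.55
  )
}

stim_shapes <- c("disc", "ring", "square", "diamond", "cross", "hbar", "vbar", "wedge")

#' Generate a parametric stimulus image set
#'
#' Each class is a colored shape (shape kind and hue fixed per class) on a
#' class-specific gray background; images within a class share low-level
#' statistics -- in particular, the within-class mean-luminance spread is
#' smaller than the spread across class means -- while position, size and
#' brightness jitter provide within-class variety.
#'
#' @param spec a [session_spec()] fixing `n_classes` and `images_per_class`.
#' @param side_px image side length in pixels (>= 16).
#' @param seed integer seed; the set is bit-reproducible.
#' @return an object of class `stimulus_set`: `images` is a list indexed
#'   `[[class_id + 1]][[image_id + 1]]` of `side x side x 3` arrays in
#'   `[0, 1]`.
#' @export
generate_stimulus_images <- function(spec, side_px = 32L, seed = 7L) {
  stopifnot(inherits(spec, "session_spec"))
  abort_if(side_px < 16, "side_px must be >= 16")
  k <- spec$n_classes
  hues <- (seq_len(k) - 1L) / k
  shapes <- stim_shapes[((seq_len(k) - 1L) %% length(stim_shapes)) + 1L]
  # spread class background luminances over [0.15, 0.75] in scrambled order
  bg <- 0.15 + 0.6 * ((seq_len(k) - 1L) * 7L %% k) / max(1L, k - 1L)
  images <- with_seed(seed, {
    lapply(seq_len(k), function(ci) {
      rgb_fg <- grDevices::col2rgb(grDevices::hsv(hues[ci], 0.85, 0.95)) / 255
      lapply(seq_len(spec$images_per_class), function(ii) {
        img <- array(bg[ci] + rnorm(1, 0, 0.015), dim = c(side_px, side_px, 3))
        cx <- 0.5 + runif(1, -0.12, 0.12)
        cy <- 0.5 + runif(1, -0.12, 0.12)
        r <- runif(1, 0.18, 0.28)
        m <- shape_mask(shapes[ci], side_px, cx, cy, r)
        bright <- runif(1, 0.85, 1.0)
        for (c3 in 1:3) {
          plane <- img[, , c3]
          plane[m] <- rgb_fg[c3] * bright
          img[, , c3] <- plane
        }
        img <- img + array(rnorm(side_px^2 * 3, 0, 0.01), dim = dim(img))
        pmin(pmax(img, 0), 1)
      })
    })
  })
  structure(list(images = images, spec = spec, side_px = as.integer(side_px),
                 hues = hues, shapes = shapes, bg_luminance = bg),
            class = "stimulus_set")
}

#' Mean luminance of every image in a set
#' @param set a `stimulus_set`.
#' @return data.frame with `class_id`, `image_id`, `luminance` (mean over
#'   pixels of the RGB average).
#' @export
stimulus_luminance <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  do.call(rbind, lapply(seq_along(set$images), function(ci) {
    data.frame(class_id = ci - 1L,
               image_id = seq_along(set$images[[ci]]) - 1L,
               luminance = vapply(set$images[[ci]], mean, 0))
  }))
}

#' Write a stimulus set as PNG files plus a manifest CSV
#' @param set a `stimulus_set`.
#' @param dir output directory (created if missing).
#' @return the manifest data.frame (`path`, `class_id`, `image_id`), invisibly.
#' @export
write_stimulus_images <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ci in seq_along(set$images)) {
    for (ii in seq_along(set$images[[ci]])) {
      p <- file.path(dir, sprintf("class%02d_img%02d.png", ci - 1L, ii - 1L))
      png::writePNG(set$images[[ci]][[ii]], p)
      rows[[length(rows) + 1L]] <- data.frame(path = p, class_id = ci - 1L, image_id = ii - 1L)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
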