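#' Specification for a synthetic digit-like dataset
#'
#' Describes a generator of labeled grayscale images with the coarse
#' statistics of handwritten-digit data: a dark background, a sparse set
#' of bright smooth strokes per class, 256 gray levels, and intra-class
#' variability from translation/rotation jitter and pixel noise. The
#' generator makes the whole pipeline testable without downloading real
#' data; real IDX files can be substituted via [read_idx()].
#'
#' @param n_classes Number of classes (labels `0..n_classes-1`).
#' @param image_size Pixels per side (square images).
#' @param n_train,n_test Sample counts for the two splits.
#' @param stroke_count Length-2 integer range: strokes per class prototype.
#' @param jitter_px Maximum absolute translation, pixels (integer shifts).
#' @param jitter_deg Maximum absolute rotation, degrees.
#' @param noise_sigma Additive pixel-noise standard deviation, gray levels.
#' @param cor_ceiling Maximum allowed pairwise correlation between class
#'   prototypes; prototypes are regenerated until all pairs fall below it.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(n_classes = 5, n_train = 100, n_test = 20, seed = 1)
#' @export
synthetic_spec <- function(n_classes = 10, image_size = 28,
                           n_train = 1000, n_test = 200,
                           stroke_count = c(2L, 4L),
                           jitter_px = 2, jitter_deg = 10,
                           noise_sigma = 12,
                           cor_ceiling = 0.5,
                           seed = 1L) {
  stopifnot(n_classes >= 1, image_size >= 1, n_train >= 0, n_test >= 0,
            length(stroke_count) == 2, stroke_count[1] >= 1,
            stroke_count[2] >= stroke_count[1],
            jitter_px >= 0, jitter_deg >= 0, noise_sigma >= 0)
  structure(list(
    n_classes = as.integer(n_classes), image_size = as.integer(image_size),
    n_train = as.integer(n_train), n_test = as.integer(n_test),
    stroke_count = as.integer(stroke_count),
    jitter_px = jitter_px, jitter_deg = jitter_deg,
    noise_sigma = noise_sigma, cor_ceiling = cor_ceiling,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# draw one smooth bright stroke pattern on a dark background
draw_prototype <- function(size, n_strokes) {
  img <- matrix(0, size, size)
  margin <- max(1, round(size * 0.12))
  lo <- margin + 1
  hi <- size - margin
  if (hi < lo) { lo <- 1; hi <- size }
  for (s in seq_len(n_strokes)) {
    n_ctrl <- sample(2:4, 1)
    px <- stats::runif(n_ctrl, lo, hi)
    py <- stats::runif(n_ctrl, lo, hi)
    # densely interpolate the polyline and stamp pixels
    for (k in seq_len(n_ctrl - 1)) {
      len <- max(abs(px[k + 1] - px[k]), abs(py[k + 1] - py[k]))
      m <- max(2L, ceiling(len * 3))
      xs <- round(seq(px[k], px[k + 1], length.out = m))
      ys <- round(seq(py[k], py[k + 1], length.out = m))
      ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
      img[cbind(xs[ok], ys[ok])] <- 1
    }
  }
  img <- gauss_smooth(img, sigma = 0.8)
  if (max(img) > 0) img <- img / max(img)
  img
}

# separable Gaussian smoothing via shift-and-add (no imaging dependency
# needed for a 3-5 tap kernel on tiny images)
gauss_smooth <- function(img, sigma = 0.8) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in -r:r) {
      if (abs(i) >= nrow(m)) next
      src <- m
      if (i > 0) {
        src <- rbind(matrix(0, i, ncol(m)), m[seq_len(nrow(m) - i), , drop = FALSE])
      } else if (i < 0) {
        src <- rbind(m[(1 - i):nrow(m), , drop = FALSE], matrix(0, -i, ncol(m)))
      }
      out <- out + k[i + r + 1] * src
    }
    out
  }
  t(smooth_1d(t(smooth_1d(img))))
}

#' Class prototype images
#'
#' Generates one prototype per class: a distinct pattern of smoothed
#' random strokes on a dark background, scaled to the full 8-bit range.
#' Prototypes are redrawn until every pairwise Pearson correlation falls
#' below `cor_ceiling`, which guarantees the classes are separable.
#'
#' @param spec A [synthetic_spec()].
#' @param max_retries Redraw budget before giving up.
#' @return A list of `image_size x image_size` integer matrices in
#'   \[0, 255\], one per class.
#' @export
make_prototypes <- function(spec, max_retries = 200L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_preserved_seed(spec$seed, {
    protos <- vector("list", spec$n_classes)
    for (cl in seq_len(spec$n_classes)) {
      ns <- sample(spec$stroke_count[1]:spec$stroke_count[2], 1)
      protos[[cl]] <- draw_prototype(spec$image_size, ns)
    }
    too_similar <- function(p) {
      if (length(p) < 2) return(integer(0))
      flat <- vapply(p, as.vector, numeric(spec$image_size^2))
      cc <- tryCatch(suppressWarnings(stats::cor(flat)),
                     error = function(e) matrix(1, length(p), length(p)))
      cc[!is.finite(cc)] <- 1  # constant images cannot be told apart
      diag(cc) <- 0
      which(apply(cc, 2, max) >= spec$cor_ceiling)
    }
    tries <- 0L
    repeat {
      bad <- too_similar(protos)
      if (length(bad) == 0) break
      tries <- tries + 1L
      if (tries > max_retries) {
        stop("could not generate class prototypes below the correlation ",
             "ceiling (", spec$cor_ceiling, ") after ", max_retries,
             " retries", call. = FALSE)
      }
      cl <- bad[1]
      ns <- sample(spec$stroke_count[1]:spec$stroke_count[2], 1)
      protos[[cl]] <- draw_prototype(spec$image_size, ns)
    }
    lapply(protos, function(p) {
      m <- matrix(as.integer(round(p * 255)), spec$image_size, spec$image_size)
      m
    })
  })
}

# nearest-neighbour rotation about the image centre; outside pixels -> 0
rotate_nn <- function(img, degrees) {
  if (degrees == 0) return(img)
  s <- nrow(img)
  th <- degrees * pi / 180
  ctr <- (s + 1) / 2
  idx <- expand.grid(r = seq_len(s), c = seq_len(s))
  dr <- idx$r - ctr
  dc <- idx$c - ctr
  src_r <- round(ctr + cos(th) * dr + sin(th) * dc)
  src_c <- round(ctr - sin(th) * dr + cos(th) * dc)
  out <- matrix(0L, s, s)
  ok <- src_r >= 1 & src_r <= s & src_c >= 1 & src_c <= s
  out[cbind(idx$r[ok], idx$c[ok])] <- img[cbind(src_r[ok], src_c[ok])]
  out
}

shift_int <- function(img, dr, dc) {
  s <- nrow(img)
  out <- matrix(0L, s, s)
  rs <- seq_len(s) + dr
  cs <- seq_len(s) + dc
  ok_r <- rs >= 1 & rs <= s
  ok_c <- cs >= 1 & cs <= s
  out[rs[ok_r], cs[ok_c]] <- img[which(ok_r), which(ok_c)]
  out
}

#' Sample a labeled synthetic dataset
#'
#' Draws `n` samples: each is its class prototype with a small random
#' integer translation, a small rotation, and additive Gaussian pixel
#' noise, clipped to \[0, 255\]. Classes are balanced to within one
#' sample and the presentation order is shuffled.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of samples; defaults to `spec$n_train`.
#' @param prototypes Optional prototype list (recomputed from the spec
#'   if missing).
#' @param split_seed_offset Offset added to the spec seed so train/test
#'   splits draw independent jitter and noise.
#' @return A tibble with an `image` list-column (integer matrices) and an
#'   integer `label` column in `0..n_classes-1`.
#' @examples
#' sp <- synthetic_spec(n_classes = 3, n_train = 30, seed = 7)
#' ds <- sample_dataset(sp)
#' table(ds$label)
#' @export
sample_dataset <- function(spec, n = spec$n_train, prototypes = NULL,
                           split_seed_offset = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 0)
  if (is.null(prototypes)) prototypes <- make_prototypes(spec)
  with_preserved_seed(spec$seed + 1000L + split_seed_offset, {
    labels <- rep_len(seq_len(spec$n_classes) - 1L, n)
    labels <- sample(labels)
    images <- lapply(labels, function(lab) {
      img <- prototypes[[lab + 1L]]
      if (spec$jitter_deg > 0) {
        img <- rotate_nn(img, stats::runif(1, -spec$jitter_deg, spec$jitter_deg))
      }
      if (spec$jitter_px > 0) {
        img <- shift_int(img,
                         sample(-spec$jitter_px:spec$jitter_px, 1),
                         sample(-spec$jitter_px:spec$jitter_px, 1))
      }
      if (spec$noise_sigma > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                            nrow(img))
      }
      matrix(as.integer(pmin(255, pmax(0, round(img)))), nrow(img))
    })
    tibble::tibble(image = images, label = as.integer(labels))
  })
}

# run code under a fixed seed without clobbering the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Read and write IDX containers
#'
#' The IDX format is the standard container for handwritten-digit
#' datasets: a big-endian header (magic `0x00000803` for 3-D image
#' tensors, `0x00000801` for 1-D label vectors) followed by big-endian
#' dimension sizes and a row-major unsigned-byte payload.
#'
#' `write_idx()` accepts either an integer vector of labels or a list of
#' equal-sized integer image matrices (values 0-255). `read_idx()`
#' validates the magic number and dimensionality and returns the same
#' representation, so `read_idx(write_idx(x))` is the identity.
#'
#' @param x Labels (integer vector) or images (list of integer matrices).
#' @param path File path.
#' @return `read_idx()`: an integer vector (labels) or a list of integer
#'   matrices (images). `write_idx()`: the path, invisibly.
#' @export
write_idx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.list(x)) {
    stopifnot(length(x) > 0)
    h <- nrow(x[[1]])
    w <- ncol(x[[1]])
    writeBin(0x00000803L, con, size = 4, endian = "big")
    writeBin(c(length(x), h, w), con, size = 4, endian = "big")
    for (img in x) {
      stopifnot(nrow(img) == h, ncol(img) == w,
                all(img >= 0), all(img <= 255))
      # IDX stores images row-major
      writeBin(as.raw(as.integer(t(img))), con)
    }
  } else {
    x <- as.integer(x)
    stopifnot(all(x >= 0), all(x <= 255))
    writeBin(0x00000801L, con, size = 4, endian = "big")
    writeBin(length(x), con, size = 4, endian = "big")
    writeBin(as.raw(x), con)
  }
  invisible(path)
}

#' @rdname write_idx
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) != 1) {
    stop("IDX format error at offset 0: truncated magic number", call. = FALSE)
  }
  if (magic == 0x00000801) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    if (length(n) != 1) {
      stop("IDX format error at offset 4: truncated dimension", call. = FALSE)
    }
    payload <- readBin(con, "raw", n)
    if (length(payload) != n) {
      stop("IDX format error at offset 8: truncated payload (expected ",
           n, " bytes, got ", length(payload), ")", call. = FALSE)
    }
    as.integer(payload)
  } else if (magic == 0x00000803) {
    dims <- readBin(con, "integer", 3, size = 4, endian = "big")
    if (length(dims) != 3) {
      stop("IDX format error at offset 4: truncated dimensions", call. = FALSE)
    }
    n <- dims[1]; h <- dims[2]; w <- dims[3]
    payload <- readBin(con, "raw", n * h * w)
    if (length(payload) != n * h * w) {
      stop("IDX format error at offset 16: truncated payload", call. = FALSE)
    }
    vals <- as.integer(payload)
    lapply(seq_len(n), function(i) {
      off <- (i - 1) * h * w
      # payload is row-major; fill by row
      matrix(vals[off + seq_len(h * w)], nrow = h, ncol = w, byrow = TRUE)
    })
  } else {
    stop(sprintf(
      "IDX format error at offset 0: unknown magic 0x%08x (expected 0x00000801 or 0x00000803)",
      magic), call. = FALSE)
  }
}
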