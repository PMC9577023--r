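# Datasets: the noisy linear regression task, a synthetic digit-glyph image
# generator (an MNIST-like fixture so the classification pipeline runs
# without downloads), and a reader for the standard MNIST IDX/ubyte files.

#' Generate the noisy linear regression dataset
#'
#' `x` is uniform on `[-1, 1]`; `y = x + noise_sd * eps` with standard
#' normal `eps`. The benchmark configuration is 50 points with
#' `noise_sd = 0.3`.
#'
#' @param n_points Number of points (>= 2).
#' @param noise_sd Noise scale (>= 0); 0 gives the noiseless line y = x.
#' @param seed Optional integer seed.
#' @return An object of class `regression_data`: list with `x`, `y`,
#'   `noise_sd`, `seed`.
#' @export
make_regression_data <- function(n_points = 50L, noise_sd = 0.3,
                                 seed = NULL) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2)
    stop_field("n_points", "must be a single integer >= 2")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop_field("noise_sd", "must be a single non-negative number")
  n <- as.integer(n_points)
  dat <- with_seed(seed, {
    x <- stats::runif(n, -1, 1)
    y <- x + noise_sd * stats::rnorm(n)
    list(x = x, y = y)
  })
  structure(c(dat, list(noise_sd = noise_sd, seed = seed)),
            class = "regression_data")
}

#' Train/test split for the regression task
#'
#' Training and testing sets are independent draws from the same generative
#' law (the testing set is a fresh point set, fixed per run).
#'
#' @param n_train,n_test Set sizes (benchmark: 50 and 50).
#' @param noise_sd Noise scale.
#' @param seed Optional integer seed (train and test use derived
#'   substreams).
#' @return List with `train` and `test` `regression_data` objects.
#' @export
make_regression_split <- function(n_train = 50L, n_test = 50L,
                                  noise_sd = 0.3, seed = NULL) {
  list(train = make_regression_data(n_train, noise_sd,
                                    derive_seed(seed, "train")),
       test = make_regression_data(n_test, noise_sd,
                                   derive_seed(seed, "test")))
}

# 5 x 7 digit skeletons (rows top to bottom), one string per row.
glyph_font <- list(
  c("01110","10001","10011","10101","11001","10001","01110"),
  c("00100","01100","00100","00100","00100","00100","01110"),
  c("01110","10001","00001","00010","00100","01000","11111"),
  c("11111","00010","00100","00010","00001","10001","01110"),
  c("00010","00110","01010","10010","11111","00010","00010"),
  c("11111","10000","11110","00001","00001","10001","01110"),
  c("00110","01000","10000","11110","10001","10001","01110"),
  c("11111","00001","00010","00100","01000","01000","01000"),
  c("01110","10001","10001","01110","10001","10001","01110"),
  c("01110","10001","10001","01111","00001","00010","01100")
)

# Render the 28 x 28 skeleton of digit d (0-9): the 5x7 bitmap upscaled x3
# (15 x 21) and centered. Returns a 28 x 28 matrix in [0, 1], rows = top
# down.
glyph_skeleton <- function(d) {
  rows <- glyph_font[[d + 1L]]
  bm <- t(vapply(rows, function(r) as.numeric(strsplit(r, "")[[1]]),
                 numeric(5)))
  big <- bm[rep(seq_len(7), each = 3L), rep(seq_len(5), each = 3L)]
  img <- matrix(0, 28, 28)
  img[4:24, 7:21] <- big
  img
}

shift_image <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Generate synthetic digit-like glyph images
#'
#' A programmatic MNIST stand-in: ten class-distinct digit skeletons
#' rendered at 28 x 28, with per-image random integer translation (up to
#' +/- 3 px), intensity scaling, and additive Gaussian pixel noise, clipped
#' to `[0, 1]`. Classes are separable by a small network; the generator
#' emulates MNIST's format (28 x 28 grayscale, labels 0-9), not its
#' handwriting variability.
#'
#' @param n_per_class Images per digit class (>= 1).
#' @param seed Optional integer seed. Different seeds change jitter and
#'   noise, not the underlying skeletons.
#' @param noise_sd Pixel noise standard deviation (default 0.15).
#' @return An object of class `image_data`: `images` (28 x 28 x n array,
#'   values in `[0, 1]`), `labels` (integer 0-9), `source =
#'   "synthetic_glyphs"`.
#' @export
make_synthetic_glyphs <- function(n_per_class = 100L, seed = NULL,
                                  noise_sd = 0.15) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L ||
      n_per_class < 1)
    stop_field("n_per_class", "must be a single integer >= 1")
  n_per_class <- as.integer(n_per_class)
  n <- 10L * n_per_class
  labels <- rep(0:9, each = n_per_class)
  skel <- lapply(0:9, glyph_skeleton)
  images <- with_seed(seed, {
    arr <- array(0, c(28L, 28L, n))
    dx <- sample(-3:3, n, replace = TRUE)
    dy <- sample(-3:3, n, replace = TRUE)
    amp <- stats::runif(n, 0.7, 1)
    for (i in seq_len(n)) {
      img <- amp[i] * shift_image(skel[[labels[i] + 1L]], dx[i], dy[i])
      img <- img + stats::rnorm(784L, sd = noise_sd)
      arr[, , i] <- pmin(pmax(img, 0), 1)
    }
    arr
  })
  structure(list(images = images, labels = labels,
                 source = "synthetic_glyphs"),
            class = "image_data")
}

#' @export
print.image_data <- function(x, ...) {
  cat(sprintf("Image dataset (%s): %d images of %d x %d, %d classes\n",
              x$source, dim(x$images)[3], dim(x$images)[1],
              dim(x$images)[2], length(unique(x$labels))))
  invisible(x)
}

#' Glyph train/test split
#'
#' Independent draws of [make_synthetic_glyphs()] for training and testing.
#'
#' @param n_train_per_class,n_test_per_class Images per class in each set
#'   (benchmark scale: 100 and 100, i.e. 1,000 + 1,000 images).
#' @param seed Optional integer seed.
#' @return List with `train` and `test` `image_data` objects.
#' @export
make_glyph_split <- function(n_train_per_class = 100L,
                             n_test_per_class = 100L, seed = NULL) {
  list(train = make_synthetic_glyphs(n_train_per_class,
                                     derive_seed(seed, "train")),
       test = make_synthetic_glyphs(n_test_per_class,
                                    derive_seed(seed, "test")))
}

# Read one IDX/ubyte file (plain or gzipped) into an array of its stated
# dimensions (first dimension = items).
read_idx <- function(file) {
  con <- gzfile(file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (magic[1] != 0L || magic[2] != 0L || magic[3] != 8L)
    stop_field("file", "not an unsigned-byte IDX file (bad magic number)")
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  n_total <- prod(dims)
  raw <- readBin(con, "integer", n = n_total, size = 1L, signed = FALSE)
  if (length(raw) != n_total)
    stop_field("file", "truncated IDX payload")
  if (ndim == 1L) return(raw)
  # IDX stores row-major; fill reversed dims then keep item index last
  arr <- array(raw, dim = rev(dims))
  aperm(arr, ndim:1)
}

#' Read MNIST IDX image and label files
#'
#' Standard IDX/ubyte format (optionally gzipped). Images are returned
#' normalized to `[0, 1]` as a 28 x 28 x n array (row = image row).
#'
#' @param file Path to an `*-images-idx3-ubyte[.gz]` or
#'   `*-labels-idx1-ubyte[.gz]` file.
#' @return For images, a 28 x 28 x n numeric array; for labels, an integer
#'   vector.
#' @export
read_idx_images <- function(file) {
  arr <- read_idx(file)
  if (length(dim(arr)) != 3L)
    stop_field("file", "expected a rank-3 image file")
  aperm(arr, c(2L, 3L, 1L)) / 255
}

#' @rdname read_idx_images
#' @export
read_idx_labels <- function(file) {
  as.integer(read_idx(file))
}

#' Load a reduced MNIST dataset from IDX files
#'
#' Randomly selects `n_train` training and `n_test` testing samples from the
#' full files (benchmark: 1,000 + 1,000). Looks for the standard file names
#' (`train-images-idx3-ubyte`, `train-labels-idx1-ubyte`,
#' `t10k-images-idx3-ubyte`, `t10k-labels-idx1-ubyte`, optionally `.gz`)
#' under `dir`.
#'
#' @param dir Directory containing the four MNIST IDX files.
#' @param n_train,n_test Subset sizes.
#' @param seed Optional integer seed for the random selection.
#' @return List with `train` and `test` `image_data` objects
#'   (`source = "mnist_files"`).
#' @export
load_mnist <- function(dir, n_train = 1000L, n_test = 1000L, seed = NULL) {
  find1 <- function(stem) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop_field("dir", sprintf("MNIST file '%s[.gz]' not found", stem))
  }
  pick <- function(img_stem, lab_stem, n, sub_seed) {
    imgs <- read_idx_images(find1(img_stem))
    labs <- read_idx_labels(find1(lab_stem))
    idx <- with_seed(sub_seed, sample.int(dim(imgs)[3], n))
    structure(list(images = imgs[, , idx, drop = FALSE], labels = labs[idx],
                   source = "mnist_files"),
              class = "image_data")
  }
  list(train = pick("train-images-idx3-ubyte", "train-labels-idx1-ubyte",
                    n_train, derive_seed(seed, "train")),
       test = pick("t10k-images-idx3-ubyte", "t10k-labels-idx1-ubyte",
                   n_test, derive_seed(seed, "test")))
}
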