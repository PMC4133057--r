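# Configuration, image IO, solution persistence, and report generation.

config_defaults <- list(
  grid = c(15L, 15L),
  ratio = NULL,
  M = NULL,
  exponent = 2,
  covariance = NULL,
  blur_sigma = 0,
  sensory_snr_db = 10,
  neural_snr_db = 10,
  constraint = list(kind = "none", gamma = 0.1, q = 0.5),
  seed = 1L,
  outdir = "."
)

known_config_keys <- names(config_defaults)

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration, fills defaults (neural SNR 10 dB,
#' spectral exponent 2, no blur), rejects unknown keys, and validates ranges.
#' The declared sensory SNR range is -60 to 60 dB (the standard sweep is -10
#' to 20 dB).
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("load_config: unsupported config extension '", ext, "'"))
  if (!is.list(cfg)) stop("load_config: config must be a mapping/object")
  unknown <- setdiff(names(cfg), known_config_keys)
  if (length(unknown) > 0) {
    stop("load_config: unknown config keys: ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(config_defaults, cfg, keep.null = TRUE)
  validate_config(out)
}

validate_config <- function(cfg) {
  g <- cfg$grid
  if (length(g) != 2 || any(!is.finite(g)) || any(g < 1) || any(g != round(g))) {
    stop("config field 'grid': must be two positive integers")
  }
  cfg$grid <- as.integer(g)
  if (!is.null(cfg$ratio) && cfg$ratio <= 0) {
    stop("config field 'ratio': must be > 0")
  }
  if (!is.null(cfg$M) && (cfg$M < 1 || cfg$M != round(cfg$M))) {
    stop("config field 'M': must be an integer >= 1")
  }
  if (cfg$exponent <= 0) stop("config field 'exponent': must be > 0")
  if (cfg$blur_sigma < 0) stop("config field 'blur_sigma': must be >= 0")
  if (cfg$sensory_snr_db < -60 || cfg$sensory_snr_db > 60) {
    stop("config field 'sensory_snr_db': outside declared range [-60, 60]")
  }
  kinds <- c("none", "weight_sparsity", "response_sparsity", "locality")
  if (!cfg$constraint$kind %in% kinds) {
    stop("config field 'constraint$kind': must be one of ",
         paste(kinds, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#' @param cfg A `run_config` (or plain list of config fields).
#' @param path Destination `.json`, `.yaml`, or `.yml` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  attributes(cfg) <- list(names = names(cfg))
  switch(ext,
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(cfg, path),
    stop("save_config: unsupported config extension '", ext, "'"))
  invisible(path)
}

#' Build a coding problem from a run configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return List with `problem`, `signal`, `blur`, and `constraint`
#'   (a [constraint_spec] or `NULL`).
#' @export
problem_from_config <- function(cfg) {
  grid <- grid_geometry(cfg$grid[1], cfg$grid[2])
  signal <- if (!is.null(cfg$covariance)) {
    load_covariance(cfg$covariance)
  } else {
    make_powerlaw_spectrum(grid, cfg$exponent)
  }
  blur <- if (cfg$blur_sigma > 0) gaussian_blur(signal, cfg$blur_sigma) else NULL
  M <- if (!is.null(cfg$M)) cfg$M else if (!is.null(cfg$ratio)) {
    population_for_ratio(signal$n, cfg$ratio)
  } else signal$n
  problem <- coding_problem(signal, blur, M = M,
                            sensory_snr_db = cfg$sensory_snr_db,
                            neural_snr_db = cfg$neural_snr_db)
  constraint <- if (cfg$constraint$kind == "none") NULL else {
    constraint_spec(cfg$constraint$kind, gamma = cfg$constraint$gamma,
                    q = cfg$constraint$q)
  }
  list(problem = problem, signal = signal, blur = blur, constraint = constraint)
}

# ---- grayscale image IO ----------------------------------------------------

#' Read a grayscale image as zero-mean intensities
#'
#' Supports PNG (via the png package; color images are averaged to gray) and
#' plain or binary PGM (P2/P5, 8- or 16-bit).  Intensities are scaled to
#' [0, 1] and the mean is subtracted.
#'
#' @param path Image path.
#' @return Numeric matrix of zero-mean intensities.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("read_gray_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE],
                                          c(1, 2), mean)
      x
    },
    pgm = read_pgm(path),
    stop("read_gray_image: unsupported image extension '", ext, "'"))
  img - mean(img)
}

# plain (P2) and binary (P5) PGM reader, 8- or 16-bit
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("read_pgm: unexpected end of file")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("read_pgm: not a PGM file (magic ", magic, ")")
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  vals <- if (magic == "P2") {
    as.numeric(scan(con, what = numeric(), n = n, quiet = TRUE))
  } else if (maxval < 256) {
    as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE))
  } else {
    as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                       endian = "big"))
  }
  matrix(vals / maxval, h, w, byrow = TRUE)
}

#' Write a matrix as an 8-bit grayscale PNG
#'
#' Values are affinely rescaled to span [0, 1].
#'
#' @param mat Numeric matrix.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(mat, path) {
  rng <- range(mat)
  x <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0 + 0.5
  png::writePNG(x, path)
  invisible(path)
}

#' Extract zero-meaned patches from an image
#'
#' @param img Numeric matrix (e.g. from [read_gray_image()]).
#' @param grid [grid_geometry] giving the patch shape.
#' @param n Number of patches.
#' @param seed Integer seed for patch locations.
#' @return `n x (patch pixels)` matrix (column-major pixel order), each patch
#'   zero-meaned.
#' @export
sample_patches <- function(img, grid, n, seed = 1) {
  H <- grid$height; W <- grid$width
  if (nrow(img) < H || ncol(img) < W) stop("sample_patches: image smaller than patch")
  withr::with_seed(seed, {
    ys <- sample.int(nrow(img) - H + 1L, n, replace = TRUE)
    xs <- sample.int(ncol(img) - W + 1L, n, replace = TRUE)
    t(vapply(seq_len(n), function(i) {
      p <- img[ys[i]:(ys[i] + H - 1L), xs[i]:(xs[i] + W - 1L)]
      as.vector(p) - mean(p)
    }, numeric(grid$n)))
  })
}

# ---- covariance / solution persistence -------------------------------------

#' Save a spectral covariance with a JSON sidecar
#'
#' The covariance goes into an RDS container; a `<path>.json` sidecar records
#' the grid, origin, and spectrum summary for humans and tooling.
#'
#' @param cov A [spectral_covariance].
#' @param path Destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_covariance <- function(cov, path) {
  stopifnot(inherits(cov, "spectral_covariance"))
  saveRDS(cov, path)
  meta <- list(n = cov$n, origin = cov$origin, basis_type = cov$basis_type,
               grid = if (!is.null(cov$grid)) c(cov$grid$height, cov$grid$width),
               trace = sum(cov$spectrum),
               md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_covariance
#' @return For `load_covariance`: the restored [spectral_covariance].
#' @export
load_covariance <- function(path) {
  if (!file.exists(path)) stop("load_covariance: file not found: ", path)
  readRDS(path)
}

#' Persist an encoder/decoder solution
#'
#' Writes the full solution (encoder, decoder, shaping state) to an RDS
#' container plus a `<path>.json` metadata sidecar (dimensions, SNRs,
#' constraint kind, md5 of the container).  Round trips are bit-exact.
#'
#' @param path Destination `.rds` path.
#' @param encoder An [encoder_solution].
#' @param decoder Optional [decoder_solution].
#' @param state Optional shaping state.
#' @param problem Optional [coding_problem] recorded for metadata.
#' @return `path`, invisibly.
#' @export
save_solution <- function(path, encoder, decoder = NULL, state = NULL,
                          problem = NULL) {
  stopifnot(inherits(encoder, "encoder_solution"))
  obj <- list(encoder = encoder, decoder = decoder, state = state)
  saveRDS(obj, path)
  meta <- list(M = nrow(encoder$W), N = ncol(encoder$W), kind = encoder$kind,
               sensory_snr_db = if (!is.null(problem)) sensory_snr_db(problem),
               neural_snr_db = if (!is.null(problem)) problem$neural_snr_db,
               md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_solution
#' @return For `load_solution`: list with `encoder`, `decoder`, `state`.
#'   Warns when the sidecar md5 does not match the container.
#' @export
load_solution <- function(path) {
  if (!file.exists(path)) stop("load_solution: file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$md5) && !identical(meta$md5, unname(tools::md5sum(path)))) {
      warning("load_solution: metadata hash does not match container: ", path)
    }
  }
  readRDS(path)
}

# ---- reports ---------------------------------------------------------------

#' Reconstruction error across population sizes
#'
#' Solves the same problem at each population size `M` and reports the
#' expected percent error of the optimal code and, where defined
#' (`M` at most the number of positive blurred-signal eigenvalues), of the
#' whitening baseline.
#'
#' @param signal A [spectral_covariance].
#' @param blur A [blur_model] or `NULL`.
#' @param sensory_snr_db Sensory SNR in dB.
#' @param Ms Integer vector of population sizes.
#' @param neural_snr_db Neural SNR in dB (default 10).
#' @return Data frame with columns `M`, `optimal_mse`, `optimal_percent`,
#'   `whitening_mse`, `whitening_percent` (NA where whitening is undefined),
#'   and `limit_mse` (the infinite-capacity bound, constant).
#' @export
sweep_population_sizes <- function(signal, blur = NULL, sensory_snr_db, Ms,
                                   neural_snr_db = 10) {
  rows <- lapply(Ms, function(M) {
    pr <- coding_problem(signal, blur, M = M, sensory_snr_db = sensory_snr_db,
                         neural_snr_db = neural_snr_db)
    sol <- solve_coding_problem(pr)
    wh_mse <- tryCatch({
      we <- whitening_encoder(pr)
      wiener_decoder(we, pr)$expected_mse
    }, error = function(e) NA_real_)
    data.frame(M = M, optimal_mse = sol$decoder$expected_mse,
               optimal_percent = sol$decoder$percent_error,
               whitening_mse = wh_mse,
               whitening_percent = 100 * wh_mse / sum(signal$spectrum),
               limit_mse = expected_mse_limit(pr))
  })
  do.call(rbind, rows)
}

#' Render CSV tables and PNG panels for a completed run
#'
#' Writes a deterministic file set into `outdir`: an error-versus-population
#' table (`error_vs_M.csv`), a per-component stage-spectra table
#' (`stage_spectra.csv`), a per-neuron receptive-field table
#' (`rf_summary.csv`), and a receptive-field mosaic (`rf_mosaic.png`).
#' Percent-error columns are written with one decimal place.  Arguments left
#' `NULL` are skipped; an empty sweep yields a header-only CSV.
#'
#' @param outdir Output directory (created if missing).
#' @param sweep Data frame from [sweep_population_sizes()] (or NULL).
#' @param spectra A [stage_spectra] data frame (or NULL).
#' @param rf_population List of [rf_summary] objects (or NULL).
#' @param geometry [grid_geometry] for the mosaic (required with
#'   `rf_population`).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(outdir, sweep = NULL, spectra = NULL,
                          rf_population = NULL, geometry = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(sweep)) {
    out <- sweep
    for (cl in grep("percent", names(out), value = TRUE)) {
      out[[cl]] <- round(out[[cl]], 1)
    }
    f <- file.path(outdir, "error_vs_M.csv")
    utils::write.csv(out, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(spectra)) {
    f <- file.path(outdir, "stage_spectra.csv")
    utils::write.csv(as.data.frame(spectra), f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(rf_population)) {
    if (is.null(geometry)) stop("render_report: rf_population needs geometry")
    tab <- data.frame(
      neuron = seq_along(rf_population),
      peak_y = vapply(rf_population, function(s) unname(s$peak["y"]), numeric(1)),
      peak_x = vapply(rf_population, function(s) unname(s$peak["x"]), numeric(1)),
      peak_value = vapply(rf_population, `[[`, numeric(1), "peak_value"),
      polarity = vapply(rf_population, `[[`, numeric(1), "sign"),
      center_pixel_count = vapply(rf_population, `[[`, numeric(1),
                                  "center_pixel_count"))
    f <- file.path(outdir, "rf_summary.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
    f <- file.path(outdir, "rf_mosaic.png")
    k <- min(length(rf_population), 25L)
    side <- ceiling(sqrt(k))
    mosaic <- matrix(0, side * geometry$height, side * geometry$width)
    for (i in seq_len(k)) {
      r <- (i - 1L) %/% side
      cc <- (i - 1L) %% side
      fld <- rf_population[[i]]$field
      rng <- max(abs(fld))
      mosaic[r * geometry$height + seq_len(geometry$height),
             cc * geometry$width + seq_len(geometry$width)] <-
        if (rng > 0) fld / (2 * rng) + 0.5 else 0.5
    }
    png::writePNG(mosaic, f)
    written <- c(written, f)
  }
  invisible(written)
}
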