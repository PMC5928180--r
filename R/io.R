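#' Read a hyperspectral cube from disk
#'
#' Supported formats:
#' * `"rds"` — the package's array container: an RDS file holding either a
#'   [hyper_cube()] or a list with elements `cube` (ny, nx, m array) and
#'   optionally `channel_axis`, `meta`, `truth` (generator ground truth).
#' * `"tiff"` — a multi-page TIFF (one grayscale page per channel) or a
#'   directory of single-page per-channel TIFFs (read in sorted name order).
#' * `"csv"` — a channels x pixels delimited-text matrix (comma-separated,
#'   header row) with a JSON sidecar `<path>.json` holding `grid_shape`
#'   (and optionally `channel_axis`).
#'
#' @param path input file (or directory for a TIFF stack).
#' @param format `"auto"` (by extension), `"rds"`, `"tiff"`, or `"csv"`.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path, format = c("auto", "rds", "tiff", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tiff"
      else switch(tolower(tools::file_ext(path)),
                  rds = "rds", tif = , tiff = "tiff", csv = "csv",
                  stop("unknown input format for ", path, call. = FALSE))
  }
  switch(format,
    rds = read_cube_rds(path),
    tiff = read_cube_tiff(path),
    csv = read_cube_csv(path)
  )
}

read_cube_rds <- function(path) {
  obj <- readRDS(path)
  if (inherits(obj, "hyper_cube")) return(obj)
  if (is.list(obj) && !is.null(obj$cube)) {
    if (inherits(obj$cube, "hyper_cube")) return(obj$cube)
    return(hyper_cube(obj$cube, channel_axis = obj$channel_axis,
                      meta = if (is.null(obj$meta)) list() else obj$meta))
  }
  stop("RDS container does not hold a cube", call. = FALSE)
}

as_gray <- function(img, path) {
  if (!is.numeric(img)) stop("non-numeric payload in ", path, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
  img
}

read_cube_tiff <- function(path) {
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF files in ", path, call. = FALSE)
    lapply(files, function(f) as_gray(tiff::readTIFF(f), f))
  } else {
    lapply(tiff::readTIFF(path, all = TRUE), as_gray, path = path)
  }
  d <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), TRUE)))
    stop("inconsistent image dimensions across the TIFF stack", call. = FALSE)
  values <- array(unlist(pages), dim = c(d[1L], d[2L], length(pages)))
  hyper_cube(values, meta = list(source = path))
}

read_cube_csv <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing grid-shape sidecar ", side, call. = FALSE)
  info <- jsonlite::read_json(side, simplifyVector = TRUE)
  X <- as.matrix(read.csv(path, header = TRUE, check.names = FALSE))
  if (!is.numeric(X)) stop("non-numeric payload in ", path, call. = FALSE)
  matrix_to_cube(data_matrix(X, grid_shape = info$grid_shape,
                             channel_axis = info$channel_axis,
                             meta = list(source = path)))
}

#' Write a cube (with optional ground truth) to the RDS array container
#' @param cube a [hyper_cube()]. @param path output `.rds` path.
#' @param truth optional [make_ground_truth()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, truth = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  saveRDS(list(cube = cube$values, channel_axis = cube$channel_axis,
               meta = cube$meta, truth = truth), path)
  invisible(path)
}

#' Read generator ground truth back from an RDS container
#' @param path container written by [write_cube()].
#' @return The `ground_truth`, or NULL when absent.
#' @export
read_ground_truth <- function(path) {
  obj <- readRDS(path)
  if (is.list(obj)) obj$truth else NULL
}

write_png_preview <- function(map, path) {
  rng <- range(map)
  img <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  png::writePNG(img, path)
  path
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Write unmixing results to a directory
#'
#' Writes `endmembers.csv` (channel axis + one column per endmember),
#' `abundance_maps.tif` (one float32 page per component, each rescaled by its
#' own maximum, recorded in the report), per-component 8-bit PNG previews
#' (min-max normalized, previews only), an optional `residual_map.tif`, and
#' `report.json` — config echo, seed, input digest, objective trace, rank
#' diagnostics, warnings, and the output file manifest.
#'
#' @param model a `factor_model`. @param outdir output directory (created).
#' @param dm optional input matrix for the residual map.
#' @param input_digest optional md5 of the input file.
#' @param extra named list merged into the report.
#' @return The report, invisibly.
#' @export
write_results <- function(model, outdir, dm = NULL, input_digest = NULL,
                          extra = list()) {
  stopifnot(inherits(model, "factor_model"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  em <- data.frame(channel = model$channel_axis %||% seq_len(nrow(model$U)))
  k <- ncol(model$U)
  for (j in seq_len(k)) em[[paste0("EM", j)]] <- model$U[, j]
  f <- file.path(outdir, "endmembers.csv")
  write.csv(em, f, row.names = FALSE)
  files <- c(files, f)

  grid <- model$grid_shape
  maps <- abundances_to_maps(model$V, grid)
  scales <- numeric(k)
  offsets <- numeric(k)  # nonzero only for sign-indefinite (PCA/SVD) maps
  pages <- vector("list", k)
  for (j in seq_len(k)) {
    mp <- unclass(maps)[, , j]
    offsets[j] <- min(mp, 0)
    mp <- mp - offsets[j]
    scales[j] <- max(mp, 0)
    pages[[j]] <- if (scales[j] > 0) mp / scales[j] else mp
  }
  f <- file.path(outdir, "abundance_maps.tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
  files <- c(files, f)
  for (j in seq_len(k)) {
    f <- file.path(outdir, sprintf("abundance_EM%d_preview.png", j))
    files <- c(files, write_png_preview(unclass(maps)[, , j], f))
  }

  if (!is.null(dm)) {
    res <- residual_map(model, dm)
    f <- file.path(outdir, "residual_map.tif")
    rmax <- max(res, 0)
    tiff::writeTIFF(if (rmax > 0) res / rmax else res, f,
                    bits.per.sample = 32L, reduce = FALSE)
    files <- c(files, f)
    extra$residual_scale <- rmax
  }

  report <- c(list(
    package = "unmixr",
    version = as.character(utils::packageVersion("unmixr")),
    method = model$method,
    k = k,
    config = unclass(model$config),
    config_digest = config_digest(model$config),
    seed = model$config$seed,
    input_digest = input_digest,
    converged = model$converged,
    iterations = model$iterations,
    objective_trace = model$objective_trace,
    abundance_tiff_scales = scales,
    abundance_tiff_offsets = offsets,
    warnings = model$warnings,
    files = basename(files)
  ), extra)
  f <- file.path(outdir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, f)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
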