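# File formats: probability maps as 8-bit grayscale PNG (value =
# round(255 * p), lossy to 1/255) or plain-text PGM (P2); boxes and
# phenotype records as CSV (comma separated, UTF-8, header mandatory,
# '.' decimal) or JSON.

#' Write an edge-probability map as an 8-bit grayscale image
#'
#' @param map numeric matrix in `[0, 1]`.
#' @param path output path; `.png` writes PNG, `.pgm` writes plain-text
#'   PGM (P2).
#' @return the path, invisibly.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(is.matrix(map), all(map >= 0 & map <= 1))
  ext <- tolower(tools::file_ext(path))
  storage.mode(map) <- "double"
  if (ext == "png") {
    png::writePNG(map, path)
  } else if (ext == "pgm") {
    v <- as.integer(round(map * 255))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(map), nrow(map)), "255"), con)
    writeLines(apply(matrix(v, nrow(map), ncol(map)), 1, paste,
                     collapse = " "), con)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' Read an edge-probability map written by [write_probability_map()]
#'
#' @param path a `.png` (8-bit gray; RGB is converted) or plain `.pgm`
#'   file.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_probability_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    return(to_gray(img))
  }
  if (ext == "pgm") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    tok <- scan(text = paste(lines[-1], collapse = " "), quiet = TRUE)
    if (trimws(lines[1]) != "P2") stop("only plain (P2) PGM is supported")
    w <- tok[1]; h <- tok[2]; mx <- tok[3]
    vals <- tok[-(1:3)]
    if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
    return(matrix(vals, h, w, byrow = TRUE) / mx)
  }
  stop("unsupported image extension: ", ext)
}

#' Read an RGB or grayscale image
#'
#' @param path PNG (via the png package) or plain PGM file.
#' @return H x W matrix or H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3 && dim(img)[3] == 4)
      img <- img[, , 1:3]  # drop alpha
    return(img)
  }
  read_probability_map(path)
}

#' Read candidate boxes from CSV or JSON
#'
#' CSV needs a header with `x_min`, `y_min`, `x_max`, `y_max` and an
#' optional `score`; JSON is an array of objects with the same keys.
#'
#' @param path input file (`.csv` or `.json`).
#' @param format `"zero_half_open"` (default: 0-based, `[min, max)`) or
#'   `"one_closed"` (1-based inclusive bounds, common in annotation tools;
#'   converted on read).
#' @return data.frame with `x_min`, `y_min`, `x_max`, `y_max`, `score`.
#' @export
read_boxes <- function(path, format = c("zero_half_open", "one_closed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  if (nrow(df) == 0) {
    df <- data.frame(x_min = numeric(0), y_min = numeric(0),
                     x_max = numeric(0), y_max = numeric(0),
                     score = numeric(0))
  }
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(df)))
    stop("boxes file must provide columns ", paste(need, collapse = ", "))
  if (is.null(df$score)) df$score <- NA_real_
  if (format == "one_closed") {
    df$x_min <- df$x_min - 1
    df$y_min <- df$y_min - 1
  }
  df[, c(need, "score")]
}

#' Write candidate boxes
#'
#' @param boxes data.frame of boxes (0-based half-open).
#' @param path output `.csv` or `.json`.
#' @return the path, invisibly.
#' @export
write_boxes <- function(boxes, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(boxes, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    utils::write.csv(boxes, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write phenotype records
#'
#' @param records data.frame from [fit_grapes_in_boxes()].
#' @param path output `.csv` or `.json`.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    utils::write.csv(records, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read phenotype records written by [write_phenotypes()]
#'
#' @param path `.csv` or `.json` file.
#' @return data.frame of records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path)
}

#' Write a synthetic scene to disk
#'
#' Writes `edge_map.png` (binary contours), `boxes.csv`, and `truth.json`
#' (ellipse parameters with z-order, visible fractions, exact areas).
#'
#' @param scene result of [generate_cluster_scene()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_probability_map(scene$edge_map, file.path(dir, "edge_map.png"))
  write_boxes(scene$truth$boxes, file.path(dir, "boxes.csv"))
  gt <- list(
    ellipses = lapply(seq_along(scene$truth$ellipses), function(i) {
      e <- scene$truth$ellipses[[i]]
      list(z = i, cx = e$cx, cy = e$cy, a = e$a, b = e$b, theta = e$theta)
    }),
    visible_fraction = scene$truth$visible_fraction,
    areas = scene$truth$areas)
  jsonlite::write_json(gt, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read the ground truth of a written scene
#'
#' @param dir directory written by [write_scene()].
#' @return list with `ellipses` (list of [ellipse()]),
#'   `visible_fraction`, `areas`.
#' @export
read_scene_truth <- function(dir) {
  gt <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                           simplifyDataFrame = TRUE)
  el <- gt$ellipses
  list(ellipses = lapply(seq_len(nrow(el)), function(i)
         ellipse(el$cx[i], el$cy[i], el$a[i], el$b[i], el$theta[i])),
       visible_fraction = gt$visible_fraction,
       areas = gt$areas)
}
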