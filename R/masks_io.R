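# Mask and study I/O: binary segmentation masks (PNG / 2-D NRRD label maps),
# grayscale base images, and the crossed images x observers study dataset.

TUMOUR_TYPES <- c("metastasis", "HGG", "LGG")
STAGES <- c("before", "during", "completion")
GRADES <- c("attending", "fellow", "resident")
EXPERIENCE_BANDS <- c("<10", "10-25", "25-50", ">50")

#' Construct a binary segmentation mask
#'
#' A `mask_image` is one observer's binary segmentation of one image on a
#' fixed pixel grid: an integer matrix with 1 = tumour, 0 = not tumour,
#' 0-based row-major orientation with the origin at the top-left. Any
#' nonzero input value is coerced to 1, so multi-label inputs become the
#' union of their regions. An all-zero mask is valid: observers are free to
#' segment nothing.
#'
#' @param pixels numeric or integer matrix; nonzero entries are foreground.
#' @param image_id,observer_id identifiers attached to the mask.
#' @return An object of class `mask_image` with fields `image_id`,
#'   `observer_id` and `pixels` (integer 0/1 matrix).
#' @examples
#' m <- mask_image(matrix(c(0, 255, 0, 255), 2, 2), "img1", "obs1")
#' sum(m$pixels)
#' @export
mask_image <- function(pixels, image_id, observer_id) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (any(!is.finite(pixels))) stop("`pixels` contains non-finite values")
  px <- matrix(as.integer(pixels != 0), nrow = nrow(pixels), ncol = ncol(pixels))
  structure(
    list(image_id = as.character(image_id),
         observer_id = as.character(observer_id),
         pixels = px),
    class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image> image %s / observer %s, %d x %d px, %d foreground\n",
              x$image_id, x$observer_id, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels)))
  invisible(x)
}

mask_grid <- function(mask) dim(mask$pixels)

#' Read a segmentation mask from disk
#'
#' Supports 8-bit grayscale PNG and 2-D NRRD label maps (the 3D Slicer
#' export dialect: any positive label is foreground, so multi-label maps are
#' ingested as the union of their labels). RGB/multi-channel PNGs are
#' rejected rather than silently flattened.
#'
#' @param path path to a `.png` or `.nrrd` file.
#' @param image_id,observer_id identifiers to attach.
#' @return A [mask_image].
#' @export
read_mask <- function(path, image_id, observer_id) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      arr <- png::readPNG(path)
      if (length(dim(arr)) != 2)
        stop("RGB/multi-channel PNG mask not supported (", path,
             "): supply an 8-bit grayscale mask; no channel is chosen silently")
      arr
    },
    nrrd = {
      arr <- read_nrrd_2d(path)
      arr
    },
    stop("unsupported mask format '.", ext, "' (expected .png or .nrrd): ", path))
  mask_image(px, image_id, observer_id)
}

#' Write a segmentation mask to disk
#'
#' Round-trips exactly: `read_mask(write_mask(m, p), ...)` reproduces `m`'s
#' pixels bit-for-bit for both formats.
#'
#' @param mask a [mask_image].
#' @param path output path.
#' @param format `"png"` or `"nrrd"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = tolower(tools::file_ext(path))) {
  stopifnot(inherits(mask, "mask_image"))
  format <- match.arg(format, c("png", "nrrd"))
  if (format == "png") {
    png::writePNG(mask$pixels * 1.0, target = path)
  } else {
    write_nrrd_2d(mask$pixels, path)
  }
  invisible(path)
}

#' Read a grayscale base image
#'
#' @param path PNG path (grayscale).
#' @return Numeric matrix with intensities in \[0, 255\].
#' @export
read_base_image <- function(path) {
  if (!file.exists(path)) stop("base image does not exist: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    # tolerate gray encoded as identical channels; reject genuine colour
    ch <- dim(arr)[3]
    rgb <- arr[, , seq_len(min(ch, 3)), drop = FALSE]
    if (max(abs(sweep(rgb, c(1, 2), rgb[, , 1]))) > 1e-9)
      stop("base image is not grayscale: ", path)
    arr <- arr[, , 1]
  }
  arr * 255
}

write_base_image <- function(base, path) {
  png::writePNG(pmin(pmax(base, 0), 255) / 255, target = path)
  invisible(path)
}

# ---- minimal 2-D NRRD codec (3D Slicer-style label maps) --------------------
# Header per the NRRD0004 format: key: value lines, blank line, then data.
# Supported: dimension 2; uint8/int8/uint16/int16/int32/uint32 types;
# raw, ascii/text and gzip encodings; little or big endian. The first axis
# in `sizes` is the fastest (x = columns), matching raster row-major order.

read_nrrd_2d <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-5]$", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- read_header_line(con)
    if (is.null(line) || line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (!identical(dimn, 2L)) stop("only 2-D NRRD label maps are supported, got dimension ", dimn)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  w <- sizes[1]; h <- sizes[2]
  type <- tolower(fields[["type"]])
  enc <- tolower(fields[["encoding"]])
  n <- w * h
  vals <- if (enc %in% c("ascii", "text", "txt")) {
    txt <- readChar(con, nchars = 1e7, useBytes = TRUE)
    as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else {
    raw_payload <- readBin(con, "raw", n = file.size(path))
    if (enc %in% c("gzip", "gz")) raw_payload <- memDecompress(raw_payload, type = "gzip")
    else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
    decode_nrrd_binary(raw_payload, type, n, fields[["endian"]])
  }
  if (length(vals) < n) stop("NRRD data truncated: expected ", n, " values, got ", length(vals))
  # x (columns) fastest: fill by row
  matrix(vals[seq_len(n)], nrow = h, ncol = w, byrow = TRUE)
}

read_header_line <- function(con) {
  bytes <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) return(if (length(bytes)) rawToChar(bytes) else NULL)
    if (b == as.raw(10)) return(sub("\r$", "", rawToChar(bytes)))
    bytes <- c(bytes, b)
  }
}

decode_nrrd_binary <- function(payload, type, n, endian_field) {
  endian <- if (is.null(endian_field)) "little" else tolower(endian_field)
  spec <- switch(type,
    "uchar" = , "uint8" = , "unsigned char" = list(size = 1, signed = FALSE),
    "char" = , "int8" = , "signed char" = list(size = 1, signed = TRUE),
    "ushort" = , "uint16" = list(size = 2, signed = FALSE),
    "short" = , "int16" = list(size = 2, signed = TRUE),
    "int" = , "int32" = list(size = 4, signed = TRUE),
    "uint" = , "uint32" = list(size = 4, signed = FALSE),
    stop("unsupported NRRD type: ", type))
  if (spec$size == 1 && !spec$signed) return(as.integer(payload[seq_len(n)]))
  readBin(payload, "integer", n = n, size = spec$size, signed = spec$signed,
          endian = endian)
}

write_nrrd_2d <- function(pixels, path, encoding = "raw") {
  stopifnot(is.matrix(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  header <- paste0(
    "NRRD0004\n",
    "type: uint8\n",
    "dimension: 2\n",
    "sizes: ", w, " ", h, "\n",
    "encoding: ", encoding, "\n",
    "endian: little\n",
    "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  payload <- as.raw(as.integer(t(pixels)))  # x fastest
  if (encoding == "raw") {
    writeBin(payload, con)
  } else if (encoding %in% c("gzip", "gz")) {
    writeBin(memCompress(payload, type = "gzip"), con)
  } else if (encoding %in% c("ascii", "text")) {
    writeChar(paste(as.integer(t(pixels)), collapse = " "), con, eos = NULL)
  } else stop("unsupported NRRD encoding: ", encoding)
  invisible(path)
}

# ---- study design -----------------------------------------------------------

#' Construct and validate a study design
#'
#' The design crosses images (each with a tumour type and operative stage)
#' with observers (each with a grade and an iUS experience band). In the
#' canonical design the nine images form a full 3 tumour types x 3 stages
#' grid, so `(tumour_type, stage)` pairs must be unique across images.
#'
#' The experience contrast is binary: observers with `>50` cases are "high",
#' `<10` are "low"; the middle bands (`10-25`, `25-50`) are excluded from
#' experience comparisons.
#'
#' @param images data.frame with columns `image_id`, `tumour_type`
#'   (metastasis/HGG/LGG) and `stage` (before/during/completion).
#' @param observers data.frame with columns `observer_id`, `grade`
#'   (attending/fellow/resident) and `experience_band`
#'   (`<10`, `10-25`, `25-50`, `>50`).
#' @return An object of class `study_design`.
#' @export
study_design <- function(images, observers) {
  images <- as.data.frame(images, stringsAsFactors = FALSE)
  observers <- as.data.frame(observers, stringsAsFactors = FALSE)
  need_i <- c("image_id", "tumour_type", "stage")
  need_o <- c("observer_id", "grade", "experience_band")
  if (!all(need_i %in% names(images)))
    stop("`images` needs columns: ", paste(need_i, collapse = ", "))
  if (!all(need_o %in% names(observers)))
    stop("`observers` needs columns: ", paste(need_o, collapse = ", "))
  images[need_i] <- lapply(images[need_i], as.character)
  observers[need_o] <- lapply(observers[need_o], as.character)
  bad_t <- setdiff(images$tumour_type, TUMOUR_TYPES)
  if (length(bad_t)) stop("unknown tumour_type: ", paste(bad_t, collapse = ", "))
  bad_s <- setdiff(images$stage, STAGES)
  if (length(bad_s)) stop("unknown stage: ", paste(bad_s, collapse = ", "))
  bad_g <- setdiff(observers$grade, GRADES)
  if (length(bad_g)) stop("unknown grade: ", paste(bad_g, collapse = ", "))
  bad_b <- setdiff(observers$experience_band, EXPERIENCE_BANDS)
  if (length(bad_b)) stop("unknown experience_band: ", paste(bad_b, collapse = ", "))
  if (anyDuplicated(images$image_id)) stop("duplicate image_id in design")
  if (anyDuplicated(observers$observer_id)) stop("duplicate observer_id in design")
  cell <- paste(images$tumour_type, images$stage)
  if (anyDuplicated(cell))
    stop("duplicate (tumour_type, stage) cell in design: ",
         cell[duplicated(cell)][1])
  structure(list(images = images, observers = observers),
            class = "study_design")
}

#' Binary high/low experience flag for observers
#'
#' @param design a [study_design].
#' @return Character vector parallel to `design$observers`: `"high"` for
#'   the `>50`-cases band, `"low"` for `<10`, `NA` for the middle bands
#'   (excluded from the experience contrast).
#' @export
experience_flag <- function(design) {
  b <- design$observers$experience_band
  out <- rep(NA_character_, length(b))
  out[b == ">50"] <- "high"
  out[b == "<10"] <- "low"
  names(out) <- design$observers$observer_id
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d images (%d tumour types x %d stages), %d observers\n",
              nrow(x$images), length(unique(x$images$tumour_type)),
              length(unique(x$images$stage)), nrow(x$observers)))
  invisible(x)
}

#' Assemble a validated study dataset
#'
#' @param design a [study_design].
#' @param masks named list of [mask_image], names `"image_id/observer_id"`;
#'   a mask must exist for every design cell.
#' @param base_images named list (by image_id) of grayscale matrices in
#'   \[0, 255\], or `NULL` entries where no base still is available.
#' @param difficulty data.frame with columns `image_id`, `observer_id`,
#'   `rating` (Likert integer 1 = very easy .. 10 = very hard).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(design, masks, base_images, difficulty) {
  stopifnot(inherits(design, "study_design"))
  cells <- expand.grid(image_id = design$images$image_id,
                       observer_id = design$observers$observer_id,
                       stringsAsFactors = FALSE)
  keys <- paste(cells$image_id, cells$observer_id, sep = "/")
  missing <- setdiff(keys, names(masks))
  if (length(missing))
    stop("missing mask for (image, observer) cell(s): ",
         paste(utils::head(missing, 5), collapse = "; "),
         if (length(missing) > 5) sprintf(" ... and %d more", length(missing) - 5))
  extra <- setdiff(names(masks), keys)
  if (length(extra))
    stop("mask present for unknown cell(s): ", paste(utils::head(extra, 5), collapse = "; "))
  # per-image grid consistency, including against the base image
  for (img in design$images$image_id) {
    grids <- lapply(design$observers$observer_id, function(o)
      mask_grid(masks[[paste(img, o, sep = "/")]]))
    ref <- grids[[1]]
    for (k in seq_along(grids)) {
      if (!identical(grids[[k]], ref))
        stop(sprintf("grid mismatch for image %s: observer %s has %dx%d, expected %dx%d",
                     img, design$observers$observer_id[k],
                     grids[[k]][1], grids[[k]][2], ref[1], ref[2]))
    }
    b <- base_images[[img]]
    if (!is.null(b) && !identical(dim(b), ref))
      stop(sprintf("base image grid for %s is %dx%d but masks are %dx%d",
                   img, nrow(b), ncol(b), ref[1], ref[2]))
  }
  difficulty <- as.data.frame(difficulty, stringsAsFactors = FALSE)
  if (nrow(difficulty)) {
    if (!all(c("image_id", "observer_id", "rating") %in% names(difficulty)))
      stop("`difficulty` needs columns image_id, observer_id, rating")
    r <- difficulty$rating
    if (any(!is.finite(r)) || any(r < 1 | r > 10) || any(r != round(r)))
      stop("difficulty ratings must be integers in [1, 10]")
    difficulty$rating <- as.integer(r)
  }
  structure(list(design = design, masks = masks,
                 base_images = base_images, difficulty = difficulty),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  print(x$design)
  cat(sprintf("  %d masks, %d difficulty ratings\n",
              length(x$masks), nrow(x$difficulty)))
  invisible(x)
}

#' Retrieve one mask from a study dataset
#' @param dataset a [study_dataset].
#' @param image_id,observer_id cell identifiers.
#' @return The [mask_image] for that cell.
#' @export
get_mask <- function(dataset, image_id, observer_id) {
  m <- dataset$masks[[paste(image_id, observer_id, sep = "/")]]
  if (is.null(m)) stop("no mask for cell (", image_id, ", ", observer_id, ")")
  m
}

image_masks <- function(dataset, image_id) {
  lapply(dataset$design$observers$observer_id,
         function(o) get_mask(dataset, image_id, o))
}

# ---- study load / write -----------------------------------------------------

#' Load a full study from a JSON config
#'
#' The config enumerates images (with tumour type, stage, optional base
#' image path and one mask path per observer), observers and the difficulty
#' table; mask paths are resolved relative to the config file. Every
#' (image, observer) cell must have a mask — a missing cell is a hard error
#' naming the cell, never a silent skip.
#'
#' @param config_path path to a study JSON (the format [write_study] emits).
#' @return A validated [study_dataset].
#' @seealso [write_study()] for the on-disk layout.
#' @export
load_study <- function(config_path) {
  if (!file.exists(config_path)) stop("study config does not exist: ", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = FALSE)
  root <- dirname(normalizePath(config_path))
  obs <- do.call(rbind, lapply(cfg$observers, function(o)
    data.frame(observer_id = o$observer_id, grade = o$grade,
               experience_band = o$experience_band, stringsAsFactors = FALSE)))
  imgs <- do.call(rbind, lapply(cfg$images, function(im)
    data.frame(image_id = im$image_id, tumour_type = im$tumour_type,
               stage = im$stage, stringsAsFactors = FALSE)))
  design <- study_design(imgs, obs)
  masks <- list()
  base_images <- list()
  for (im in cfg$images) {
    for (oid in design$observers$observer_id) {
      p <- im$masks[[oid]]
      if (is.null(p))
        stop("config lists no mask for cell (", im$image_id, ", ", oid, ")")
      masks[[paste(im$image_id, oid, sep = "/")]] <-
        read_mask(file.path(root, p), im$image_id, oid)
    }
    base_images[[im$image_id]] <-
      if (!is.null(im$base_image)) read_base_image(file.path(root, im$base_image)) else NULL
  }
  difficulty <- if (length(cfg$difficulty)) {
    do.call(rbind, lapply(cfg$difficulty, function(d)
      data.frame(image_id = d$image_id, observer_id = d$observer_id,
                 rating = d$rating, stringsAsFactors = FALSE)))
  } else data.frame(image_id = character(), observer_id = character(),
                    rating = integer())
  study_dataset(design, masks, base_images, difficulty)
}

#' Write a study dataset to disk
#'
#' Emits `study.json` plus `masks/<image>__<observer>.<fmt>` and
#' `base/<image>.png` under `dir`. `load_study()` on the emitted JSON
#' round-trips the dataset exactly (pixelwise-equal masks, identical design
#' and ratings).
#'
#' @param dataset a [study_dataset].
#' @param dir output directory (created if needed).
#' @param mask_format `"png"` or `"nrrd"`.
#' @return Path to the written `study.json`, invisibly.
#' @export
write_study <- function(dataset, dir, mask_format = c("png", "nrrd")) {
  mask_format <- match.arg(mask_format)
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "base"), recursive = TRUE, showWarnings = FALSE)
  d <- dataset$design
  images_json <- lapply(seq_len(nrow(d$images)), function(i) {
    img <- d$images$image_id[i]
    mask_paths <- list()
    for (oid in d$observers$observer_id) {
      rel <- file.path("masks", paste0(img, "__", oid, ".", mask_format))
      write_mask(get_mask(dataset, img, oid), file.path(dir, rel), mask_format)
      mask_paths[[oid]] <- rel
    }
    entry <- list(image_id = img,
                  tumour_type = d$images$tumour_type[i],
                  stage = d$images$stage[i],
                  masks = mask_paths)
    b <- dataset$base_images[[img]]
    if (!is.null(b)) {
      rel <- file.path("base", paste0(img, ".png"))
      write_base_image(b, file.path(dir, rel))
      entry$base_image <- rel
    }
    entry
  })
  observers_json <- lapply(seq_len(nrow(d$observers)), function(i)
    as.list(d$observers[i, , drop = FALSE]))
  difficulty_json <- lapply(seq_len(nrow(dataset$difficulty)), function(i)
    as.list(dataset$difficulty[i, , drop = FALSE]))
  cfg_path <- file.path(dir, "study.json")
  jsonlite::write_json(
    list(images = images_json, observers = observers_json,
         difficulty = difficulty_json),
    cfg_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg_path)
}
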