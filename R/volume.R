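#' Image volumes and label maps
#'
#' `image_volume()` wraps a 3D scalar grid (Hounsfield-unit scale) together
#' with its geometry: voxel spacing (mm), world origin (mm) and a 3x3
#' direction matrix whose columns are the world directions of the grid
#' axes. The internal world frame is LPS. `label_map()` is the binary
#' counterpart used for lumen/aorta masks; values must be 0/1.
#'
#' Voxel centers sit at `origin + direction %*% ((index - 1) * spacing)`
#' with 1-based indices. No operation in the package resamples a grid
#' implicitly; mismatched grids raise errors.
#'
#' @param data 3D numeric array.
#' @param spacing positive numeric length-3, mm.
#' @param origin numeric length-3, mm (LPS).
#' @param direction 3x3 matrix with orthonormal columns.
#' @return An object of class `image_volume` (or `label_map`).
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(!is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
label_map <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3)) {
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("label map must contain only values 0 and 1")
  vol <- image_volume(data * 1.0, spacing, origin, direction)
  class(vol) <- c("label_map", "image_volume")
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param vol an `image_volume` or `label_map`.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Check two volumes share a grid
#'
#' @param a,b volumes.
#' @param tol metadata tolerance (mm).
#' @return TRUE invisibly; error describing the mismatch otherwise.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: differing dimensions")
  if (max(abs(a$spacing - b$spacing)) > tol)
    stop("grid mismatch: differing spacing")
  if (max(abs(a$origin - b$origin)) > tol)
    stop("grid mismatch: differing origin")
  if (max(abs(a$direction - b$direction)) > tol)
    stop("grid mismatch: differing orientation")
  invisible(TRUE)
}

lps_affine <- function(vol) {
  A <- cbind(vol$direction %*% diag(vol$spacing), vol$origin)
  rbind(A, c(0, 0, 0, 1))
}

# NIfTI stores RAS affines; internal frame is LPS.
ras_from_lps <- function(A) diag(c(-1, -1, 1, 1)) %*% A
lps_from_ras <- function(A) diag(c(-1, -1, 1, 1)) %*% A

volume_from_affine <- function(data, A_lps, as_labels = FALSE) {
  M <- A_lps[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2, spacing, "/")
  if (as_labels) label_map(data, spacing, A_lps[1:3, 4], direction)
  else image_volume(data, spacing, A_lps[1:3, 4], direction)
}

is_nrrd <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)

#' Read and write volumes (NIfTI-1 or NRRD)
#'
#' The format is chosen from the file extension (`.nii`, `.nii.gz`,
#' `.nrrd`). Grid metadata round-trips within float tolerance; the world
#' frame is converted to LPS on read. `read_labels()` additionally
#' validates that the grid holds only 0/1.
#'
#' @param path file path.
#' @return `image_volume` / `label_map`.
#' @export
read_volume <- function(path) {
  if (is_nrrd(path)) return(read_nrrd(path))
  img <- RNifti::readNifti(path)
  A <- lps_from_ras(structure(RNifti::xform(img), dim = c(4, 4)))
  data <- array(as.numeric(img), dim = dim(img)[1:3])
  volume_from_affine(data, A)
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  vol <- read_volume(path)
  vals <- unique(as.vector(vol$data))
  if (!all(vals %in% c(0, 1)))
    stop("label file contains values other than 0/1: ",
         paste(head(setdiff(vals, c(0, 1))), collapse = ", "))
  label_map(vol$data, vol$spacing, vol$origin, vol$direction)
}

#' @rdname read_volume
#' @param vol volume to write.
#' @export
write_volume <- function(vol, path) {
  if (is_nrrd(path)) return(write_nrrd(vol, path))
  A_ras <- ras_from_lps(lps_affine(vol))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`sform<-`(img, structure(A_ras, code = 2L))
  img <- RNifti::`qform<-`(img, structure(A_ras, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_labels <- function(vol, path) write_volume(vol, path)

# ---- minimal NRRD (3D, raw / gzip encodings) -------------------------------

nrrd_types <- c(double = "double", float = "float", short = "short",
                `unsigned short` = "ushort", uchar = "uchar",
                `unsigned char` = "uchar", int = "int",
                `unsigned int` = "uint", uint8 = "uchar", int16 = "short",
                uint16 = "ushort", int32 = "int", float32 = "float",
                float64 = "double")

nrrd_bytes <- c(double = 8, float = 4, short = 2, ushort = 2, uchar = 1,
                int = 4, uint = 4)

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  t(sapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), USE.NAMES = FALSE))
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line))
    parts <- strsplit(line, ":=?")[[1]]
    fields[[tolower(trimws(parts[1]))]] <- trimws(paste(parts[-1], collapse = ":"))
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  type <- nrrd_types[[tolower(fields$type)]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields$type)
  n <- prod(sizes)
  enc <- tolower(fields$encoding)
  raw_data <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) raw_data <- memDecompress(raw_data, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", fields$encoding)
  endian <- if (!is.null(fields$endian) && fields$endian == "big") "big" else "little"
  what <- if (type %in% c("double", "float")) "numeric" else "integer"
  data <- readBin(raw_data, what, n = n, size = nrrd_bytes[[type]],
                  signed = !(type %in% c("uchar", "ushort")), endian = endian)
  arr <- array(as.numeric(data), dim = sizes)

  dirs <- if (!is.null(fields[["space directions"]]))
    t(parse_nrrd_vectors(fields[["space directions"]])) else diag(3)
  origin <- if (!is.null(fields[["space origin"]]))
    as.numeric(parse_nrrd_vectors(fields[["space origin"]])) else c(0, 0, 0)
  space <- tolower(fields$space %||% "left-posterior-superior")
  if (space %in% c("right-anterior-superior", "ras")) {
    dirs[1:2, ] <- -dirs[1:2, ]
    origin[1:2] <- -origin[1:2]
  } else if (!space %in% c("left-posterior-superior", "lps")) {
    stop("unsupported NRRD space: ", fields$space)
  }
  A <- rbind(cbind(dirs, origin), c(0, 0, 0, 1))
  volume_from_affine(arr, A)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_nrrd <- function(vol, path) {
  M <- vol$direction %*% diag(vol$spacing)
  dirvec <- apply(M, 2, function(v) sprintf("(%g,%g,%g)", v[1], v[2], v[3]))
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(dim(vol$data), collapse = " ")),
           paste("space directions:", paste(dirvec, collapse = " ")),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           sprintf("space origin: (%g,%g,%g)",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Reorient a volume to canonical LPS axes
#'
#' Permutes and flips grid axes so the direction matrix becomes (close to)
#' the identity in the LPS frame. World coordinates of every voxel are
#' unchanged; the operation is idempotent.
#'
#' @param vol an `image_volume` or `label_map`.
#' @return reoriented volume of the same class.
#' @export
reorient_to_lps <- function(vol) {
  D <- vol$direction
  if (abs(det(D)) < 1e-8) stop("singular direction matrix")
  perm <- apply(abs(D), 1, which.max)
  if (length(unique(perm)) != 3) stop("degenerate direction matrix")
  signs <- sapply(1:3, function(a) sign(D[a, perm[a]]))

  d <- dim(vol$data)
  idx <- lapply(1:3, function(a) if (signs[a] < 0) rev(seq_len(d[perm[a]]))
                else seq_len(d[perm[a]]))
  data <- aperm(vol$data, perm)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

  # world coordinate of the new first voxel
  first_old <- ifelse(signs < 0, d[perm], 1)
  old_ijk <- integer(3)
  old_ijk[perm] <- first_old
  origin_new <- as.numeric(voxel_world(vol, matrix(old_ijk, nrow = 1)))
  dir_new <- D[, perm] %*% diag(signs)
  spacing_new <- vol$spacing[perm]
  if (inherits(vol, "label_map"))
    label_map(data, spacing_new, origin_new, dir_new)
  else image_volume(data, spacing_new, origin_new, dir_new)
}
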