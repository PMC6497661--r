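# Landmark dataset container and file I/O.
#
# CSV dialect (long format): specimen,species,landmark,x,y,z with empty
# coordinate fields for missing landmarks; the landmark column is 1-based.
# Curve-spec JSON uses 0-based landmark ids:
#   {"curves":[{"ids":[...],"fixed_ends":true}], "pairs":[[l,r],...],
#    "midline":[...]}

#' Construct a landmark dataset
#'
#' @param coords specimen x landmark x 3 numeric array.
#' @param specimens Character specimen ids (defaults to dimnames or s1..sn).
#' @param species Character species per specimen.
#' @param mask specimen x landmark logical missingness mask; defaults to the
#'   non-finite cells of `coords`.
#' @param curves List of `list(ids = <ordered landmark indices>,
#'   fixed_ends = TRUE)`; endpoints of every curve are fixed landmarks.
#' @param bilateral_pairs Two-column matrix of (left, right) indices.
#' @param midline Integer indices of midline landmarks.
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, specimens = NULL, species = NULL,
                             mask = NULL, curves = NULL,
                             bilateral_pairs = NULL, midline = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  n <- dim(coords)[1]; k <- dim(coords)[2]
  if (is.null(specimens))
    specimens <- dimnames(coords)[[1]] %||% sprintf("s%d", seq_len(n))
  if (is.null(species)) species <- specimens
  stopifnot(length(specimens) == n, length(species) == n)
  if (is.null(mask)) mask <- !apply(is.finite(coords), c(1, 2), all)
  stopifnot(identical(dim(mask), c(n, k)))
  if (any(!mask & !apply(is.finite(coords), c(1, 2), all)))
    stop("non-finite coordinates present where the mask is FALSE", call. = FALSE)
  if (!is.null(bilateral_pairs)) {
    bilateral_pairs <- as.matrix(bilateral_pairs)
    stopifnot(ncol(bilateral_pairs) == 2)
    idx <- as.vector(bilateral_pairs)
    if (anyDuplicated(idx)) stop("bilateral pairs must be disjoint", call. = FALSE)
    if (length(intersect(idx, midline)))
      stop("bilateral pairs must not include midline landmarks", call. = FALSE)
  }
  if (!is.null(curves)) {
    for (cv in curves) {
      if (any(cv$ids < 1 | cv$ids > k))
        stop("unknown landmark index in curve definition", call. = FALSE)
    }
  }
  dimnames(coords)[[1]] <- specimens
  structure(list(coords = coords, specimens = specimens, species = species,
                 mask = mask, curves = curves,
                 bilateral_pairs = bilateral_pairs,
                 midline = as.integer(midline)),
            class = "landmark_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("landmark_dataset: %d specimens, %d species, %d landmarks, %.1f%% missing\n",
              dim(x$coords)[1], length(unique(x$species)), dim(x$coords)[2],
              100 * mean(x$mask)))
  invisible(x)
}

#' Number of semilandmarks (interior curve points) in a dataset
#' @param x A `landmark_dataset`.
#' @return Integer vector of sliding landmark indices.
#' @export
sliding_indices <- function(x) {
  if (is.null(x$curves)) return(integer(0))
  unique(unlist(lapply(x$curves, function(cv) {
    ids <- cv$ids
    if (isTRUE(cv$fixed_ends)) ids[-c(1, length(ids))] else ids
  })))
}

#' Read landmark configurations
#'
#' @param path CSV (long dialect) or TPS file.
#' @param format `"csv"` or `"tps"`.
#' @param curve_spec_path Optional JSON file with curves/pairs/midline
#'   (0-based landmark ids).
#' @param species_map Optional named character vector specimen -> species
#'   (TPS files carry no species column).
#' @return A `landmark_dataset` with the mask set wherever coordinates are
#'   absent.
#' @export
read_landmarks <- function(path, format = c("csv", "tps"),
                           curve_spec_path = NULL, species_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("specimen", "species", "landmark", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("landmark CSV must have columns ", paste(need, collapse = ","),
           call. = FALSE)
    specs <- unique(df$specimen)
    counts <- tapply(df$landmark, df$specimen, length)[specs]
    if (length(unique(counts)) != 1) {
      tab <- table(counts)
      k_ref <- max(as.integer(names(tab)[tab == max(tab)]))
      stop("inconsistent landmark count for specimen ",
           names(counts)[which(counts != k_ref)[1]], call. = FALSE)
    }
    k <- unname(counts[1])
    coords <- array(NA_real_, c(length(specs), k, 3))
    species <- character(length(specs))
    for (i in seq_along(specs)) {
      sub <- df[df$specimen == specs[i], ]
      sub <- sub[order(sub$landmark), ]
      if (!identical(as.integer(sub$landmark), seq_len(k)))
        stop("inconsistent landmark count for specimen ", specs[i], call. = FALSE)
      coords[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
      species[i] <- sub$species[1]
    }
    ds_args <- list(coords = coords, specimens = specs, species = species)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lm_at <- grep("^LM3=", lines)
    if (!length(lm_at)) stop("no LM3 blocks in TPS file", call. = FALSE)
    ks <- as.integer(sub("^LM3=", "", lines[lm_at]))
    if (length(unique(ks)) != 1)
      stop("inconsistent landmark count in TPS record ",
           which(ks != ks[1])[1], call. = FALSE)
    k <- ks[1]
    n <- length(lm_at)
    coords <- array(NA_real_, c(n, k, 3))
    specs <- sprintf("spec_%03d", seq_len(n))
    for (i in seq_len(n)) {
      block <- lines[(lm_at[i] + 1):(lm_at[i] + k)]
      xyz <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
      coords[i, , ] <- xyz
      j <- lm_at[i] + k + 1
      while (j <= length(lines) && !grepl("^LM3=", lines[j])) {
        if (grepl("^ID=", lines[j])) specs[i] <- sub("^ID=", "", lines[j])
        j <- j + 1
      }
    }
    species <- if (!is.null(species_map)) unname(species_map[specs]) else specs
    ds_args <- list(coords = coords, specimens = specs, species = species)
  }
  if (!is.null(curve_spec_path)) {
    spec <- read_curve_spec(curve_spec_path, k = dim(ds_args$coords)[2])
    ds_args <- c(ds_args, spec)
  }
  do.call(landmark_dataset, ds_args)
}

#' Read a curve-specification JSON file
#'
#' Landmark ids in the file are 0-based and converted to 1-based on read.
#'
#' @param path JSON file.
#' @param k Landmark count, for validation.
#' @return List with `curves`, `bilateral_pairs`, `midline`.
#' @export
read_curve_spec <- function(path, k = Inf) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- NULL
  if (!is.null(js$curves)) {
    raw <- js$curves
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    curves <- lapply(raw, function(cv) {
      ids <- unlist(cv$ids) + 1L
      if (any(ids < 1 | ids > k))
        stop("unknown landmark index in curve spec", call. = FALSE)
      list(ids = as.integer(ids), fixed_ends = isTRUE(unlist(cv$fixed_ends)))
    })
    names(curves) <- NULL
  }
  pairs <- NULL
  if (!is.null(js$pairs) && length(js$pairs)) {
    pairs <- if (is.matrix(js$pairs)) js$pairs else
      do.call(rbind, lapply(js$pairs, function(p) as.integer(unlist(p))))
    storage.mode(pairs) <- "integer"
    pairs <- pairs + 1L
    if (ncol(pairs) != 2 || any(pairs < 1 | pairs > k))
      stop("unknown landmark index in pairs", call. = FALSE)
  }
  midline <- if (!is.null(js$midline)) as.integer(unlist(js$midline)) + 1L else NULL
  list(curves = curves, bilateral_pairs = pairs, midline = midline)
}

#' Write a landmark dataset in the long CSV dialect
#'
#' @param dataset A `landmark_dataset`.
#' @param path Output CSV path.
#' @param curve_spec_path Optional path for the companion curve-spec JSON.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(dataset, path, curve_spec_path = NULL) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- dim(dataset$coords)[1]; k <- dim(dataset$coords)[2]
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))  # bit-exact round trip
  df <- data.frame(
    specimen = rep(dataset$specimens, each = k),
    species = rep(dataset$species, each = k),
    landmark = rep(seq_len(k), n),
    x = fmt(as.vector(t(dataset$coords[, , 1]))),
    y = fmt(as.vector(t(dataset$coords[, , 2]))),
    z = fmt(as.vector(t(dataset$coords[, , 3]))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(curve_spec_path)) {
    js <- list(
      curves = lapply(dataset$curves %||% list(), function(cv)
        list(ids = cv$ids - 1L, fixed_ends = cv$fixed_ends)),
      pairs = if (!is.null(dataset$bilateral_pairs))
        lapply(seq_len(nrow(dataset$bilateral_pairs)), function(i)
          as.integer(dataset$bilateral_pairs[i, ] - 1L)) else list(),
      midline = if (length(dataset$midline)) dataset$midline - 1L else list())
    jsonlite::write_json(js, curve_spec_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
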