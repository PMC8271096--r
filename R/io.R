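# Text-based persistence: tab-delimited matrices with region-label
# headers, subject bundle directories, parcellation hierarchies, and
# derived-parameter records. Values are written with 17 significant
# digits so write -> read round-trips at full double precision.

#' Write a square matrix as labelled TSV
#'
#' @param matrix Square numeric matrix.
#' @param path Output file.
#' @param labels Region labels for the header row (defaults to `r1..rN`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, labels = NULL) {
  stopifnot_square(matrix, "matrix")
  n <- ncol(matrix)
  labels <- labels %||% colnames(matrix) %||% sprintf("r%d", seq_len(n))
  lines <- c(
    paste(labels, collapse = "\t"),
    apply(matrix, 1, function(row) {
      paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled square TSV matrix
#'
#' @param path Input file written by [write_matrix()].
#' @return Numeric matrix with the header labels as dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file has no data rows", call. = FALSE)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(labels)
  rows <- lapply(seq.int(2, length(lines)), function(i) {
    vals <- suppressWarnings(
      as.numeric(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    )
    if (length(vals) != n || anyNA(vals)) {
      stop(
        sprintf(
          "line %d of '%s': expected %d numeric fields", i, path, n
        ),
        call. = FALSE
      )
    }
    vals
  })
  if (length(rows) != n) {
    stop(
      sprintf(
        "'%s' is not square: %d labels but %d rows", path, n, length(rows)
      ),
      call. = FALSE
    )
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(labels, labels)
  m
}

# deterministic FNV-1a hash of a string, for config provenance stamps
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Serialize a subject bundle to a directory
#'
#' Writes `esc.tsv`, `epl.tsv`, `bold_session{i}.tsv`, and `meta.json`
#' (TR, parcellation level, ground truth, region labels). FC matrices are
#' not stored; they are recomputed on read.
#'
#' @param bundle A `subject_bundle`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "subject_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- sprintf("r%d", seq_len(bundle$parcellation$n_regions))
  write_matrix(bundle$connectome$counts, file.path(dir, "esc.tsv"), labels)
  write_matrix(bundle$connectome$lengths, file.path(dir, "epl.tsv"), labels)
  for (i in seq_along(bundle$bold$sessions)) {
    s <- bundle$bold$sessions[[i]]
    lines <- c(
      paste(labels, collapse = "\t"),
      apply(s, 1, function(row) {
        paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
      })
    )
    writeLines(lines, file.path(dir, sprintf("bold_session%d.tsv", i)))
  }
  meta <- list(
    subject_id = bundle$subject_id,
    tr = bundle$bold$tr,
    n_sessions = length(bundle$bold$sessions),
    parcellation_level = bundle$parcellation$level_id,
    ground_truth = bundle$ground_truth
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a subject bundle directory
#'
#' @param dir Directory written by [write_bundle()].
#' @param parcellation The `parcellation` the bundle was written at.
#' @return A `subject_bundle` with recomputed eFC matrices.
#' @export
read_bundle <- function(dir, parcellation) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  counts <- read_matrix(file.path(dir, "esc.tsv"))
  lengths <- read_matrix(file.path(dir, "epl.tsv"))
  files <- file.path(dir, sprintf("bold_session%d.tsv", seq_len(meta$n_sessions)))
  sessions <- lapply(files, function(f) {
    lines <- readLines(f)
    n <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
    m <- matrix(
      as.numeric(unlist(strsplit(lines[-1], "\t", fixed = TRUE))),
      ncol = n, byrow = TRUE
    )
    m
  })
  dimnames(counts) <- dimnames(lengths) <- NULL
  subject_bundle(
    subject_id = meta$subject_id,
    parcellation = parcellation,
    connectome = new_structural_connectome(counts, lengths),
    bold = bold_dataset(sessions, meta$tr),
    ground_truth = meta$ground_truth
  )
}

#' Persist the similarity planes of a fit result
#'
#' Writes one tab-delimited matrix per target (rows = grid delays,
#' columns = couplings) plus a JSON sidecar recording the grid, subject,
#' model, and seed.
#'
#' @param result A `fit_result` from [fit_subject()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit_planes <- function(result, dir) {
  stopifnot(inherits(result, "fit_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$planes)) {
    p <- result$planes[[nm]]
    lines <- c(
      paste(formatC(result$grid$C_values, digits = 17, format = "g"),
        collapse = "\t"
      ),
      apply(p, 1, function(row) {
        paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
      })
    )
    writeLines(lines, file.path(dir, sprintf("plane_%s.tsv", nm)))
  }
  jsonlite::write_json(
    list(
      subject_id = result$subject_id,
      parcellation = result$parcellation,
      model = result$model_kind,
      seed = result$seed,
      tau_values = result$grid$tau_values,
      C_values = result$grid$C_values,
      targets = names(result$planes)
    ),
    file.path(dir, "planes.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Serialize a parcellation hierarchy to JSON
#'
#' @param hierarchy List of `parcellation`s from
#'   [make_parcellation_hierarchy()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_parcellation_hierarchy <- function(hierarchy, path) {
  levels <- lapply(hierarchy, function(p) {
    list(
      level_id = p$level_id,
      n_regions = p$n_regions,
      region_sizes = p$region_sizes,
      centroids = unname(apply(p$centroids, 1, as.list)),
      parent_map = p$parent_map
    )
  })
  jsonlite::write_json(list(levels = levels), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a parcellation hierarchy from JSON
#'
#' @param path File written by [write_parcellation_hierarchy()].
#' @return List of `parcellation`s, finest first.
#' @export
read_parcellation_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj$levels, function(lv) {
    cents <- do.call(rbind, lapply(lv$centroids, function(cc) unlist(cc)))
    colnames(cents) <- c("x", "y", "z")
    new_parcellation(
      level_id = lv$level_id,
      region_sizes = unlist(lv$region_sizes),
      centroids = cents,
      parent_map = unlist(lv$parent_map)
    )
  })
}
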