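#' A single coordinate-based experiment
#'
#' One neuroimaging experiment as archived in a coordinate database: an
#' identifier, the number of scanned subjects (which drives the spatial
#' uncertainty kernel), the reported activation foci as MNI mm coordinates,
#' and optional taxonomy labels (behavioral domains / paradigm classes).
#'
#' @param id unique experiment identifier.
#' @param n_subjects positive integer subject count.
#' @param foci n x 3 numeric matrix of mm coordinates (a length-3 vector is
#'   accepted for a single focus).
#' @param labels character vector of taxonomy labels; duplicates collapse.
#' @return An object of class `experiment`.
#' @export
experiment <- function(id, n_subjects, foci, labels = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("n_subjects must be a positive integer")
  foci <- rbind2mat(foci)
  if (ncol(foci) != 3L || nrow(foci) < 1L)
    stop("foci must be a non-empty n x 3 matrix")
  if (!all(is.finite(foci))) stop("foci coordinates must be finite")
  labels <- unique(as.character(labels))
  labels <- labels[nzchar(labels)]
  structure(list(id = id, n_subjects = n_subjects, foci = foci,
                 labels = labels),
            class = "experiment")
}

#' Coordinate database of experiments on a grid
#'
#' @param experiments list of [experiment()] objects with unique ids.
#' @param grid the [brain_grid()] the database is analyzed on.
#' @return An object of class `coordinate_database`.
#' @export
coordinate_database <- function(experiments, grid) {
  stopifnot(inherits(grid, "brain_grid"))
  if (!is.list(experiments) ||
      !all(vapply(experiments, inherits, TRUE, "experiment")))
    stop("experiments must be a list of experiment objects")
  ids <- vapply(experiments, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate experiment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(experiments = experiments, grid = grid),
            class = "coordinate_database")
}

#' @export
length.coordinate_database <- function(x) length(x$experiments)

#' @export
print.coordinate_database <- function(x, ...) {
  cat(sprintf("<coordinate_database> %d experiments, %d foci, %d labels\n",
              length(x), n_foci(x), length(db_labels(x))))
  invisible(x)
}

#' Total focus count of a database
#' @param db a `coordinate_database`.
#' @export
n_foci <- function(db) {
  sum(vapply(db$experiments, function(e) nrow(e$foci), 0L))
}

#' Experiment ids of a database
#' @param db a `coordinate_database`.
#' @export
db_ids <- function(db) vapply(db$experiments, `[[`, "", "id")

#' All taxonomy labels occurring in a database
#' @param db a `coordinate_database`.
#' @export
db_labels <- function(db) {
  sort(unique(unlist(lapply(db$experiments, `[[`, "labels"))))
}

#' Load a Sleuth-style foci text file
#'
#' The dialect: a `# Reference=MNI` header; per experiment a
#' `// <id>: Subjects=<n>` line, an optional `// Labels: a; b; c` line, then
#' one focus per line as whitespace-separated x y z in mm; blank lines
#' separate experiments. Talairach reference lines are refused outright —
#' no silent coordinate conversion.
#'
#' @param path text file path.
#' @param grid the [brain_grid()] the database will be analyzed on.
#' @return A [coordinate_database()].
#' @export
load_sleuth_database <- function(path, grid) {
  lines <- readLines(path, warn = FALSE)
  ref <- grep("^#\\s*Reference\\s*=", lines, value = TRUE)
  if (length(ref) == 0L)
    stop("missing '# Reference=MNI' header in ", path)
  space <- sub("^#\\s*Reference\\s*=\\s*", "", ref[1])
  if (toupper(trimws(space)) != "MNI")
    stop("reference space '", trimws(space),
         "' refused: only MNI coordinates are supported ",
         "(convert Talairach input upstream)")
  exps <- list()
  cur_id <- NULL; cur_n <- NA_integer_; cur_labels <- character()
  cur_foci <- list()
  flush <- function() {
    if (is.null(cur_id)) return(invisible(NULL))
    if (length(cur_foci) == 0L)
      stop("experiment '", cur_id, "' has no foci")
    exps[[length(exps) + 1L]] <<-
      experiment(cur_id, cur_n, do.call(rbind, cur_foci), cur_labels)
    cur_id <<- NULL; cur_n <<- NA_integer_
    cur_labels <<- character(); cur_foci <<- list()
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { flush(); next }
    if (grepl("^#", ln)) next
    hm <- regmatches(ln, regexec("^//\\s*(.+?)\\s*:\\s*Subjects\\s*=\\s*(-?\\d+)\\s*$", ln))[[1]]
    if (length(hm) == 3L) {
      flush()
      cur_id <- hm[2]
      cur_n <- as.integer(hm[3])
      if (cur_n < 1L) stop("line ", i, ": Subjects must be >= 1")
      next
    }
    if (grepl("^//\\s*Labels\\s*:", ln)) {
      if (is.null(cur_id)) stop("line ", i, ": Labels line outside a block")
      lab <- sub("^//\\s*Labels\\s*:\\s*", "", ln)
      cur_labels <- c(cur_labels,
                      trimws(strsplit(lab, ";", fixed = TRUE)[[1]]))
      next
    }
    if (grepl("^//", ln)) stop("line ", i, ": malformed header line: ", ln)
    xyz <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
    if (length(xyz) != 3L || any(is.na(xyz)))
      stop("line ", i, ": malformed coordinate line: ", ln)
    if (is.null(cur_id)) stop("line ", i, ": focus line outside a block")
    cur_foci[[length(cur_foci) + 1L]] <- xyz
  }
  flush()
  if (length(exps) == 0L) stop("no experiments in ", path)
  db <- coordinate_database(exps, grid)
  stopifnot(n_foci(db) == sum(vapply(exps, function(e) nrow(e$foci), 0L)))
  db
}

#' Save a database in the Sleuth-style dialect
#'
#' Output is re-loadable with identical content (ids, subject counts, foci
#' to full double precision via `%.10g`, sorted labels). Labels containing
#' the dialect's structural tokens (`//` or `;`) are rejected.
#'
#' @param db a [coordinate_database()].
#' @param path output path.
#' @export
save_sleuth_database <- function(db, path) {
  stopifnot(inherits(db, "coordinate_database"))
  out <- c("# Reference=MNI", "")
  for (e in db$experiments) {
    bad <- grepl("//", e$labels, fixed = TRUE) |
      grepl(";", e$labels, fixed = TRUE)
    if (any(bad))
      stop("labels may not contain '//' or ';': ",
           paste(e$labels[bad], collapse = ", "))
    out <- c(out, sprintf("// %s: Subjects=%d", e$id, e$n_subjects))
    if (length(e$labels))
      out <- c(out, paste0("// Labels: ",
                           paste(sort(e$labels), collapse = "; ")))
    out <- c(out, apply(e$foci, 1, function(r)
      paste(sprintf("%.10g", r), collapse = "\t")))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# 0-based voxel indices of an experiment's foci on a grid
foci_voxels <- function(exp, grid) nearest_voxel(grid, exp$foci)

#' Select the experiments reporting at least one focus inside a seed
#'
#' An experiment qualifies when any of its foci, assigned to its nearest
#' voxel, lands inside the seed mask; qualifying experiments are retained
#' whole (all their foci kept), mirroring whole-experiment selection in
#' meta-analytic connectivity modeling.
#'
#' @param db a [coordinate_database()].
#' @param seed a [seed_region()] on the same grid.
#' @return The sub-database (possibly empty, with a warning).
#' @export
select_experiments_by_seed <- function(db, seed) {
  stopifnot(inherits(db, "coordinate_database"), inherits(seed, "seed_region"))
  if (!same_grid(db$grid, seed$grid))
    stop("database and seed live on different grids")
  hit <- vapply(db$experiments, function(e) {
    v <- foci_voxels(e, db$grid)
    ok <- in_grid(db$grid, v)
    if (!any(ok)) return(FALSE)
    any(seed$mask[flat_index(db$grid, v[ok, , drop = FALSE])])
  }, TRUE)
  if (!any(hit))
    warning("no experiment reports a focus inside seed '", seed$name, "'")
  coordinate_database(db$experiments[hit], db$grid)
}
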