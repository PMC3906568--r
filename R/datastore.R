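#' Hierarchical acquisition session storage
#'
#' A session is a tree of typed directories (e.g. day / slice / cell /
#' protocol_run), each carrying a human-readable JSON index file
#' (\code{.index.json}) that records the directory's own metadata and one
#' entry per child directory and dataset. Directory types can declare
#' required metadata fields, enforced at creation. Index updates are atomic
#' (write to a temporary file, then rename). Array payloads are stored one
#' file per dataset in R's native serialization with their metadata,
#' checksummed for corruption detection; the index stays plain JSON so a
#' session is browsable with any text tools.
#'
#' @param root session root directory (created if missing).
#' @param dir_types named list: directory type name -> character vector of
#'   required metadata fields (may be empty).
#' @param metadata metadata for the root.
#' @return a \code{dir_handle} for the root.
#' @export
init_session <- function(root, dir_types = list(), metadata = list()) {
  if (!dir.exists(root)) {
    ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create session root: ", root)
  }
  if (!is.list(dir_types) ||
      (length(dir_types) && is.null(names(dir_types))))
    stop("dir_types must be a named list of required-field vectors")
  idx_path <- file.path(root, ".index.json")
  if (file.exists(idx_path)) {
    idx <- .read_index(root)
    if (length(dir_types)) {
      idx$dir_types <- utils::modifyList(idx$dir_types %||% list(),
                                         lapply(dir_types, as.list))
      .write_index(root, idx)
    }
  } else {
    idx <- list(dir_type = "session_root",
                metadata = metadata,
                dir_types = lapply(dir_types, as.list),
                children = stats::setNames(list(), character()),
                datasets = stats::setNames(list(), character()))
    .write_index(root, idx)
  }
  .dir_handle(root, root, "session_root")
}

.dir_handle <- function(path, root, dir_type) {
  structure(list(path = path, root = root, dir_type = dir_type),
            class = "dir_handle")
}

#' @export
print.dir_handle <- function(x, ...) {
  cat("<dir_handle>", x$dir_type, "at", x$path, "\n")
  invisible(x)
}

.read_index <- function(path) {
  f <- file.path(path, ".index.json")
  if (!file.exists(f)) stop("no index file in ", path)
  jsonlite::fromJSON(f, simplifyVector = FALSE)
}

.write_index <- function(path, idx) {
  f <- file.path(path, ".index.json")
  tmp <- tempfile("index", tmpdir = path, fileext = ".json.tmp")
  writeLines(jsonlite::toJSON(idx, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", digits = NA), tmp)
  file.rename(tmp, f)
  invisible(f)
}

.session_types <- function(handle) {
  .read_index(handle$root)$dir_types %||% list()
}

.unique_name <- function(existing, name) {
  if (!name %in% existing) return(name)
  k <- 0L
  repeat {
    cand <- sprintf("%s_%03d", name, k)
    if (!cand %in% existing) return(cand)
    k <- k + 1L
  }
}

#' Create a typed child directory
#'
#' Validates required metadata fields for the directory type, creates the
#' directory with its own index, and records it in the parent index
#' atomically. Name collisions are resolved with numeric suffixes
#' (\code{_000}, \code{_001}, ...).
#'
#' @param parent a \code{dir_handle}.
#' @param dir_type registered directory type name.
#' @param metadata named list of metadata (must include the type's required
#'   fields).
#' @param name base directory name (default: the type name).
#' @return a \code{dir_handle} for the new directory.
#' @export
create_child_dir <- function(parent, dir_type, metadata = list(),
                             name = dir_type) {
  types <- .session_types(parent)
  req <- types[[dir_type]]
  if (is.null(req) && length(types))
    stop("unregistered directory type: '", dir_type, "'")
  missing_f <- setdiff(unlist(req), names(metadata))
  if (length(missing_f))
    stop("missing required metadata for type '", dir_type, "': ",
         paste(missing_f, collapse = ", "))
  pidx <- .read_index(parent$path)
  nm <- .unique_name(names(pidx$children), name)
  dir.create(file.path(parent$path, nm))
  cidx <- list(dir_type = dir_type, metadata = metadata,
               children = stats::setNames(list(), character()),
               datasets = stats::setNames(list(), character()))
  .write_index(file.path(parent$path, nm), cidx)
  pidx$children[[nm]] <- list(dir_type = dir_type, metadata = metadata)
  .write_index(parent$path, pidx)
  .dir_handle(file.path(parent$path, nm), parent$root, dir_type)
}

#' Open an existing child directory
#' @param parent a \code{dir_handle}.
#' @param name child directory name.
#' @export
open_child_dir <- function(parent, name) {
  pidx <- .read_index(parent$path)
  if (is.null(pidx$children[[name]]))
    stop("no child directory '", name, "' in ", parent$path)
  .dir_handle(file.path(parent$path, name), parent$root,
              pidx$children[[name]]$dir_type)
}

#' Metadata of a directory
#' @param handle a \code{dir_handle}.
#' @export
dir_metadata <- function(handle) .read_index(handle$path)$metadata

#' Write an array payload with metadata
#'
#' Stores the payload (numeric array, \code{trace} or \code{frame_series})
#' in one file with its metadata and an MD5 checksum, and lists it in the
#' directory index. Duplicate names get numeric suffixes.
#'
#' @param dir a \code{dir_handle}.
#' @param name dataset name.
#' @param payload array, \code{trace}, or \code{frame_series}.
#' @param metadata named list of additional metadata.
#' @return the dataset record (list with \code{name}, \code{file},
#'   \code{kind}, \code{md5}).
#' @export
write_array <- function(dir, name, payload, metadata = list()) {
  kind <- if (inherits(payload, "trace")) "trace" else
    if (inherits(payload, "frame_series")) "frame_series" else "array"
  vals <- switch(kind, trace = payload$samples,
                 frame_series = payload$frames, payload)
  if (is.numeric(vals) && !all(is.finite(vals[!is.na(vals)])))
    stop("payload contains non-finite values")
  if (kind == "trace")
    metadata <- c(metadata, list(rate = payload$rate, t0 = payload$t0,
                                 units = payload$units,
                                 channel = payload$channel))
  if (kind == "frame_series")
    metadata <- c(metadata,
                  list(frame_times = payload$times,
                       exposure = payload$exposure,
                       transform = as.vector(unclass(payload$transform)),
                       objective = payload$objective))
  idx <- .read_index(dir$path)
  nm <- .unique_name(names(idx$datasets), name)
  file <- paste0(nm, ".rds")
  fpath <- file.path(dir$path, file)
  saveRDS(list(kind = kind, payload = payload, metadata = metadata),
          fpath, version = 3)
  md5 <- unname(tools::md5sum(fpath))
  rec <- list(name = nm, file = file, kind = kind, md5 = md5,
              shape = if (is.null(dim(vals))) length(vals) else dim(vals),
              metadata = metadata[!vapply(metadata, is.function, logical(1))])
  rec_idx <- rec
  rec_idx$metadata <- lapply(rec_idx$metadata, function(m)
    if (inherits(m, "transform3d")) as.vector(unclass(m)) else m)
  idx$datasets[[nm]] <- rec_idx
  .write_index(dir$path, idx)
  invisible(rec)
}

#' Read an array payload back
#'
#' Verifies the stored checksum and reconstructs the payload with its
#' metadata, bit-exact.
#' @param dir a \code{dir_handle}.
#' @param name dataset name.
#' @return list with \code{payload}, \code{metadata}, \code{kind}.
#' @export
read_array <- function(dir, name) {
  idx <- .read_index(dir$path)
  rec <- idx$datasets[[name]]
  if (is.null(rec)) stop("no dataset '", name, "' in ", dir$path)
  fpath <- file.path(dir$path, rec$file)
  if (!file.exists(fpath)) stop("payload file missing for '", name, "'")
  md5 <- unname(tools::md5sum(fpath))
  if (!identical(md5, rec$md5))
    stop("checksum mismatch for dataset '", name,
         "' (file corrupted?): ", md5, " != ", rec$md5)
  obj <- readRDS(fpath)
  list(payload = obj$payload, metadata = obj$metadata, kind = obj$kind)
}

#' Store every recorded trace / frame series of a task result
#' @param dir a \code{dir_handle} (e.g. a protocol_run directory).
#' @param result a \code{task_result}.
#' @export
store_task_result <- function(dir, result) {
  for (dv in names(result$results)) {
    entry <- result$results[[dv]]
    for (ch in names(entry)) {
      v <- entry[[ch]]
      if (inherits(v, "trace") || inherits(v, "frame_series"))
        write_array(dir, paste(dv, ch, sep = "."), v,
                    metadata = list(device = dv, channel = ch,
                                    status = result$status))
    }
  }
  invisible(dir)
}

#' Check index / directory consistency of a session subtree
#'
#' Walks the tree and verifies that every index entry corresponds to an
#' existing directory or payload file and vice versa (fsck-style).
#' @param handle a \code{dir_handle}.
#' @return character vector of inconsistencies (empty when clean).
#' @export
verify_session <- function(handle) {
  problems <- character()
  walk <- function(path) {
    idx <- tryCatch(.read_index(path), error = function(e) NULL)
    if (is.null(idx)) {
      problems <<- c(problems, paste0("unreadable index: ", path))
      return()
    }
    on_disk <- list.dirs(path, recursive = FALSE, full.names = FALSE)
    for (ch in names(idx$children)) {
      if (!ch %in% on_disk)
        problems <<- c(problems, paste0("indexed child missing: ",
                                        file.path(path, ch)))
    }
    for (d in on_disk) {
      if (!d %in% names(idx$children))
        problems <<- c(problems, paste0("unindexed directory: ",
                                        file.path(path, d)))
    }
    for (ds in names(idx$datasets)) {
      f <- file.path(path, idx$datasets[[ds]]$file)
      if (!file.exists(f))
        problems <<- c(problems, paste0("indexed dataset missing: ", f))
    }
    files <- setdiff(list.files(path, pattern = "\\.rds$"), character())
    listed <- vapply(idx$datasets, `[[`, character(1), "file")
    for (f in files) {
      if (!f %in% listed)
        problems <<- c(problems, paste0("unindexed dataset: ",
                                        file.path(path, f)))
    }
    for (ch in names(idx$children)) walk(file.path(path, ch))
  }
  walk(handle$path)
  problems
}
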