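# Benchmark filename convention: me2-<dataset>_<split><XX>[_<channel>].nii.gz
# Images carry a 4-digit channel suffix (e.g. _0000); labels do not.
file_pattern <- "^me2-[A-Za-z0-9]+_(train|test)[0-9]+(_[0-9]{4})?\\.nii\\.gz$"
channel_pattern <- "_[0-9]{4}\\.nii\\.gz$"

case_id_of <- function(filename) {
  sub("\\.nii\\.gz$", "", sub(channel_pattern, ".nii.gz", filename))
}

list_cases <- function(dir) {
  if (!dir.exists(dir)) return(character(0))
  sort(list.files(dir, pattern = "\\.nii\\.gz$"))
}

#' Read and validate an nnU-Net-compatible dataset layout
#'
#' Expects `root` to contain `dataset.json` plus `imagesTr/`, `labelsTr/`
#' and optionally `imagesTs/`, `labelsTs/`, `split.json`, `metadata.csv`
#' and a checksum manifest. Validates that every file matches the
#' `me2-<dataset>_<split>XX[_<channel>].nii.gz` convention, that images
#' carry a channel suffix and labels do not, that every image has its label
#' (and vice versa), and that the train/val/test splits are pairwise
#' disjoint. All violations are collected and reported together.
#'
#' Without `split.json`, splits are inferred from folder membership
#' (imagesTr = train, imagesTs = test, no validation cases). Unknown keys
#' of `dataset.json` are preserved verbatim under `$json`.
#'
#' @param root dataset directory.
#' @return An object of class `dataset_descriptor`: `name`, `channel_names`,
#'   `spacing`, case-id vectors `train`, `val`, `test`, data.frame `files`
#'   (case, image, label, folder), `metadata` (data.frame or NULL), `json`
#'   (the raw dataset.json), `root`.
#' @export
read_dataset_descriptor <- function(root) {
  dj_path <- file.path(root, "dataset.json")
  if (!file.exists(dj_path))
    stop("dataset.json not found under ", root, call. = FALSE)
  dj <- tryCatch(jsonlite::read_json(dj_path),
                 error = function(e) stop("malformed dataset.json: ",
                                          conditionMessage(e), call. = FALSE))
  problems <- character(0)
  imgsTr <- list_cases(file.path(root, "imagesTr"))
  labsTr <- list_cases(file.path(root, "labelsTr"))
  imgsTs <- list_cases(file.path(root, "imagesTs"))
  labsTs <- list_cases(file.path(root, "labelsTs"))

  for (f in c(imgsTr, labsTr, imgsTs, labsTs))
    if (!grepl(file_pattern, f))
      problems <- c(problems, sprintf("filename does not match convention: %s", f))
  for (f in c(imgsTr, imgsTs))
    if (!grepl(channel_pattern, f))
      problems <- c(problems, sprintf("image lacks channel suffix: %s", f))
  for (f in c(labsTr, labsTs))
    if (grepl(channel_pattern, f))
      problems <- c(problems, sprintf("label carries a channel suffix: %s", f))

  pair_up <- function(imgs, labs, folder) {
    icase <- unique(case_id_of(imgs))
    lcase <- case_id_of(labs)
    for (ca in setdiff(icase, lcase))
      problems <<- c(problems, sprintf("image without label in %s: %s", folder, ca))
    for (ca in setdiff(lcase, icase))
      problems <<- c(problems, sprintf("label without image in %s: %s", folder, ca))
    common <- intersect(icase, lcase)
    if (length(common) == 0L)
      return(data.frame(case = character(0), image = character(0),
                        label = character(0), folder = character(0)))
    data.frame(case = common,
               image = vapply(common, function(ca)
                 imgs[case_id_of(imgs) == ca][1L], character(1)),
               label = vapply(common, function(ca)
                 labs[lcase == ca][1L], character(1)),
               folder = folder, row.names = NULL)
  }
  files <- rbind(pair_up(imgsTr, labsTr, "Tr"), pair_up(imgsTs, labsTs, "Ts"))

  sj_path <- file.path(root, "split.json")
  if (file.exists(sj_path)) {
    sj <- tryCatch(jsonlite::read_json(sj_path, simplifyVector = TRUE),
                   error = function(e) stop("malformed split.json: ",
                                            conditionMessage(e), call. = FALSE))
    train <- as.character(sj$train %||% character(0))
    val <- as.character(sj$val %||% sj$validation %||% character(0))
    test <- as.character(sj$test %||% character(0))
    for (pair in list(c("train", "val"), c("train", "test"), c("val", "test"))) {
      ov <- intersect(get(pair[1]), get(pair[2]))
      if (length(ov))
        problems <- c(problems, sprintf("split overlap between %s and %s: %s",
                                        pair[1], pair[2], paste(ov, collapse = ", ")))
    }
    listed <- c(train, val, test)
    for (ca in setdiff(listed, files$case))
      problems <- c(problems, sprintf("split lists unknown case: %s", ca))
  } else {
    train <- files$case[files$folder == "Tr"]
    val <- character(0)
    test <- files$case[files$folder == "Ts"]
  }
  if (length(problems))
    stop("dataset layout validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  md_path <- file.path(root, "metadata.csv")
  metadata <- if (file.exists(md_path))
    read.csv(md_path, stringsAsFactors = FALSE, check.names = FALSE) else NULL

  structure(list(
    name = dj$name %||% basename(normalizePath(root)),
    channel_names = dj$channel_names %||% dj$modality %||% list(`0` = "EM"),
    spacing = as.numeric(unlist(dj$spacing %||% c(1, 1, 1))),
    train = train, val = val, test = test,
    files = files, metadata = metadata, json = dj, root = root
  ), class = "dataset_descriptor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dataset_descriptor <- function(x, ...) {
  cat(sprintf("<dataset_descriptor> %s (%s)\n", x$name, x$root))
  cat(sprintf("  cases: %d train / %d val / %d test\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

parse_manifest <- function(manifest) {
  if (is.data.frame(manifest)) {
    stopifnot(all(c("digest", "path") %in% names(manifest)))
    return(manifest[c("digest", "path")])
  }
  lines <- readLines(manifest, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([0-9a-fA-F]+)[ \t]+\\*?(.+)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("unparseable manifest line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  data.frame(digest = tolower(vapply(m, `[`, character(1), 2L)),
             path = vapply(m, `[`, character(1), 3L))
}

#' Verify file checksums against a manifest
#'
#' Recomputes each listed file's digest and reports `match`, `mismatch` or
#' `missing` per file. Missing files are report entries, never errors.
#'
#' @param root directory the manifest's relative paths resolve against.
#' @param manifest path to a plain-text manifest (one `<hex>  <relpath>`
#'   per line, the `sha256sum` format) or a data.frame with columns
#'   `digest`, `path`. Defaults to `<root>/checksums.sha256`.
#' @param algo digest algorithm (default "sha256").
#' @return data.frame with columns `path`, `expected`, `actual`, `status`;
#'   attribute `pass` is TRUE iff every file matches.
#' @export
verify_checksums <- function(root, manifest = file.path(root, "checksums.sha256"),
                             algo = "sha256") {
  man <- parse_manifest(manifest)
  actual <- character(nrow(man)); status <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    fp <- file.path(root, man$path[i])
    if (!file.exists(fp)) {
      actual[i] <- NA_character_; status[i] <- "missing"
    } else {
      actual[i] <- digest::digest(fp, algo = algo, file = TRUE)
      status[i] <- if (identical(actual[i], man$digest[i])) "match" else "mismatch"
    }
  }
  out <- data.frame(path = man$path, expected = man$digest,
                    actual = actual, status = status)
  attr(out, "pass") <- all(status == "match")
  out
}

#' Write a checksum manifest for a dataset directory
#'
#' @param root directory to scan.
#' @param files relative paths to include; defaults to every regular file
#'   under `root` except the manifest itself.
#' @param path manifest path (default `<root>/checksums.sha256`).
#' @inheritParams verify_checksums
#' @return `path`, invisibly.
#' @export
write_checksum_manifest <- function(root, files = NULL,
                                    path = file.path(root, "checksums.sha256"),
                                    algo = "sha256") {
  if (is.null(files)) {
    files <- list.files(root, recursive = TRUE)
    files <- setdiff(files, basename(path))
  }
  digests <- vapply(file.path(root, files), digest::digest,
                    character(1), algo = algo, file = TRUE)
  writeLines(sprintf("%s  %s", digests, files), path)
  invisible(path)
}
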