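#' Read a co-fractionation profile matrix
#'
#' Reads the TSV dialect used throughout the package: a `protein` id column
#' followed by one column per fraction (`fraction_1 ..`), empty cells
#' meaning missing. Missing cells are preserved as `NA`, never as zero.
#' Rows with no observed value are dropped with a warning; duplicated
#' protein ids and non-numeric cells are errors.
#'
#' @param path file path.
#' @param replicate optional replicate label stored as an attribute.
#' @return tibble `protein`, `fraction_1 .. fraction_N`.
#' @export
read_profile_matrix <- function(path, replicate = NULL) {
  stopifnot(file.exists(path))
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(), .default = readr::col_double()),
    progress = FALSE))
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    stop("non-numeric cell at row ", prob$row[1], ", column ", prob$col[1],
         " of ", path, call. = FALSE)
  }
  if (!"protein" %in% names(raw)) {
    stop("profile matrix must have a 'protein' id column", call. = FALSE)
  }
  dup <- unique(raw$protein[duplicated(raw$protein)])
  if (length(dup)) {
    stop("duplicated protein id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("profile values must be non-negative", call. = FALSE)
  }
  empty <- rowSums(!is.na(vals)) == 0
  if (any(empty)) {
    warning("dropped ", sum(empty), " all-missing profile row(s)",
            call. = FALSE)
    raw <- raw[!empty, ]
  }
  if (!is.null(replicate)) attr(raw, "replicate") <- replicate
  raw
}

#' Write a profile matrix
#' @param profiles tibble as returned by [sim_profiles()] /
#'   [read_profile_matrix()].
#' @param path file path.
#' @export
write_profile_matrix <- function(profiles, path) {
  readr::write_tsv(profiles, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write a complex list
#'
#' One complex per line: name, TAB, semicolon-separated member ids.
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_complex_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(x) strsplit(x[2], ";", fixed = TRUE)[[1]]),
           vapply(parts, `[`, character(1), 1))
}

#' @rdname read_complex_list
#' @param complexes named list of character vectors.
#' @export
write_complex_list <- function(complexes, path) {
  lines <- vapply(names(complexes), function(nm)
    paste0(nm, "\t", paste(complexes[[nm]], collapse = ";")), character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write an edge list
#'
#' TSV of canonical unordered pairs (`protein_a < protein_b`), optionally
#' with extra score columns.
#' @param path file path.
#' @return tibble with at least `protein_a`, `protein_b`.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_a = readr::col_character(), protein_b = readr::col_character(),
    .default = readr::col_guess()), progress = FALSE)
}

#' @rdname read_edge_list
#' @param edges tibble with `protein_a`, `protein_b` and optional columns.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write a two-column annotation map
#' @param path file path.
#' @return tibble `protein`, `term`.
#' @export
read_annotation_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(), term = readr::col_character()),
    progress = FALSE)
}

#' @rdname read_annotation_map
#' @param annotations tibble `protein`, `term`.
#' @export
write_annotation_map <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Read / write a protein-by-condition matrix (expression or phenotype)
#' @param path file path.
#' @return tibble `protein`, `cond_1 ..`.
#' @export
read_condition_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}

#' @rdname read_condition_matrix
#' @param mat tibble `protein`, condition columns.
#' @export
write_condition_matrix <- function(mat, path) {
  readr::write_tsv(mat, path, na = "", progress = FALSE)
  invisible(path)
}

#' Generate a complete synthetic experiment bundle
#'
#' Runs every generator off one parameter set: truth, per-replicate profile
#' matrices, co-expression and phenotype matrices, GO-like and domain-like
#' annotation maps, a partially known gold standard, and two external
#' interactomes for overlap / high-confidence logic.
#'
#' @param params a [sim_params()] object.
#' @param known_fraction gold-standard coverage of the true complexes.
#' @param coexpression,phenotypes,annotations,external optional lists of
#'   arguments forwarded to the respective generators.
#' @return list with elements `truth`, `profiles`, `coexpression`,
#'   `phenotypes`, `annotations` (list go/domain), `gold`, `external`
#'   (list of two edge tibbles), `params`.
#' @export
sim_bundle <- function(params, known_fraction = 0.6,
                       coexpression = list(), phenotypes = list(),
                       annotations = list(), external = list()) {
  truth <- sim_truth(params)
  ext_args <- modifyList(list(true_edge_recall = 0.5, false_edge_count = 200),
                         external)
  ext1 <- do.call(sim_external_interactome, c(list(truth), ext_args))
  ext2 <- do.call(sim_external_interactome,
                  c(list(truth), ext_args,
                    list(seed = (truth$streams[["external"]] + 101L) %%
                           .Machine$integer.max)))
  list(
    truth = truth,
    profiles = sim_profiles(truth),
    coexpression = do.call(sim_coexpression, c(list(truth), coexpression)),
    phenotypes = do.call(sim_phenotypes, c(list(truth), phenotypes)),
    annotations = do.call(sim_annotations, c(list(truth), annotations)),
    gold = sim_gold_standard(truth, known_fraction),
    external = list(ext1, ext2),
    params = params,
    known_fraction = known_fraction,
    args = list(coexpression = coexpression, phenotypes = phenotypes,
                annotations = annotations, external = external)
  )
}

#' Write a synthetic bundle to disk
#'
#' Persists every table of a [sim_bundle()] in the package's standard TSV
#' dialects, plus a plain-text manifest recording the seed and all generator
#' parameters; [regenerate_bundle()] on the manifest reproduces the files
#' byte-identically.
#'
#' @param bundle a [sim_bundle()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bundle$profiles)) {
    write_profile_matrix(bundle$profiles[[i]],
                         file.path(dir, sprintf("profiles_rep%d.tsv", i)))
  }
  write_complex_list(bundle$truth$complexes,
                     file.path(dir, "true_complexes.tsv"))
  write_complex_list(gold_complex_list(bundle$gold),
                     file.path(dir, "gold_complexes.tsv"))
  write_condition_matrix(bundle$coexpression,
                         file.path(dir, "coexpression.tsv"))
  write_condition_matrix(bundle$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_annotation_map(bundle$annotations$go,
                       file.path(dir, "annotations_go.tsv"))
  write_annotation_map(bundle$annotations$domain,
                       file.path(dir, "annotations_domain.tsv"))
  write_edge_list(bundle$external[[1]], file.path(dir, "external_1.tsv"))
  write_edge_list(bundle$external[[2]], file.path(dir, "external_2.tsv"))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    generator = "coelute::sim_bundle",
    seed = bundle$params$seed,
    known_fraction = bundle$known_fraction,
    params = unclass(bundle$params),
    args = bundle$args
  ), manifest, precision = 17)
  invisible(manifest)
}

#' Regenerate a fixture bundle from its manifest
#'
#' @param manifest_path path to a manifest written by
#'   [write_fixture_bundle()].
#' @param dir optional directory to re-write the bundle into.
#' @return the regenerated bundle (invisibly written to `dir` if given).
#' @export
regenerate_bundle <- function(manifest_path, dir = NULL) {
  m <- yaml::read_yaml(manifest_path)
  params <- do.call(sim_params, m$params[setdiff(names(m$params), "seed")] |>
                      c(list(seed = m$seed)))
  args <- lapply(m$args, function(x) if (is.null(x)) list() else x)
  bundle <- do.call(sim_bundle,
                    c(list(params, known_fraction = m$known_fraction), args))
  if (!is.null(dir)) write_fixture_bundle(bundle, dir)
  invisible(bundle)
}

#' Read a fixture bundle directory back into memory
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return list mirroring [sim_bundle()] minus the latent truth object
#'   (complex lists are read back as plain lists).
#' @export
read_fixture_bundle <- function(dir) {
  reps <- sort(list.files(dir, "^profiles_rep[0-9]+\\.tsv$",
                          full.names = TRUE))
  list(
    profiles = lapply(seq_along(reps), function(i)
      read_profile_matrix(reps[i], replicate = sprintf("rep%d", i))),
    true_complexes = read_complex_list(file.path(dir, "true_complexes.tsv")),
    gold = gold_standard(read_complex_list(file.path(dir,
                                                     "gold_complexes.tsv"))),
    coexpression = read_condition_matrix(file.path(dir, "coexpression.tsv")),
    phenotypes = read_condition_matrix(file.path(dir, "phenotypes.tsv")),
    annotations = list(
      go = read_annotation_map(file.path(dir, "annotations_go.tsv")),
      domain = read_annotation_map(file.path(dir, "annotations_domain.tsv"))),
    external = list(read_edge_list(file.path(dir, "external_1.tsv")),
                    read_edge_list(file.path(dir, "external_2.tsv"))),
    manifest = yaml::read_yaml(file.path(dir, "manifest.yaml"))
  )
}
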