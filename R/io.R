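#' Read and write the pipeline's tabular formats
#'
#' Plain TSV readers/writers for every table the pipeline consumes or
#' produces: marker maps (`marker`, `chrom`, `pos_cm`), paternal-inheritance
#' matrices (`animal` x markers, entries 1/2/NA), phenotypes (`animal`,
#' `trait`, `hatch`, `dam`, `body_weight`), wide expression matrices
#' (`gene_id` x animals), haplotype tables (`animal`, `subgroup`,
#' `proximal`, `distal`, `both`) and scan curves (`pos_cm`, `lrt`, `lod`
#' plus a JSON sidecar holding the maximum, threshold, support interval and
#' effect). Every writer/reader pair round-trips identically; numeric
#' columns keep full precision. Duplicate identifiers are rejected with the
#' offending values named.
#'
#' @param path File path.
#' @param x Object to write.
#' @name subtypeqtl-io
NULL

assert_unique <- function(ids, what, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s in %s: %s", what, path,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
}

#' @rdname subtypeqtl-io
#' @export
read_marker_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           marker = readr::col_character(),
                           chrom = readr::col_character(),
                           pos_cm = readr::col_double()))
  assert_unique(out$marker, "marker names", path)
  if (any(diff(out$pos_cm) < 0)) {
    stop(sprintf("markers in %s are not sorted by position", path),
         call. = FALSE)
  }
  out
}

#' @rdname subtypeqtl-io
#' @export
write_marker_map <- function(x, path) readr::write_tsv(x, path)

#' @rdname subtypeqtl-io
#' @export
read_inheritance <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_unique(out$animal, "animal ids", path)
  for (col in setdiff(names(out), "animal")) {
    v <- out[[col]]
    if (!all(is.na(v) | v %in% c(1, 2))) {
      stop(sprintf("column %s of %s has entries outside {1, 2, NA}",
                   col, path), call. = FALSE)
    }
    out[[col]] <- as.integer(v)
  }
  out
}

#' @rdname subtypeqtl-io
#' @export
write_inheritance <- function(x, path) readr::write_tsv(x, path)

#' @rdname subtypeqtl-io
#' @export
read_phenotypes <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_unique(out$animal, "animal ids", path)
  need <- c("animal", "trait", "hatch", "dam", "body_weight")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    stop(sprintf("%s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out$hatch <- factor(out$hatch)
  out$dam <- factor(out$dam)
  out
}

#' @rdname subtypeqtl-io
#' @export
write_phenotypes <- function(x, path) readr::write_tsv(x, path)

#' @rdname subtypeqtl-io
#' @export
read_expression <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_unique(out$gene_id, "gene ids", path)
  out
}

#' @rdname subtypeqtl-io
#' @export
write_expression <- function(x, path) readr::write_tsv(x, path)

#' @rdname subtypeqtl-io
#' @export
read_haplotype_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  assert_unique(out$animal, "animal ids", path)
  new_haplotype_table(out)
}

#' @rdname subtypeqtl-io
#' @export
write_haplotype_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
}

#' @rdname subtypeqtl-io
#' @export
write_scan <- function(x, path) {
  stopifnot(inherits(x, "qtl_scan"))
  readr::write_tsv(x$scan, path)
  side <- as.list(glance.qtl_scan(x))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname subtypeqtl-io
#' @export
read_scan <- function(path) {
  scan <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- structure(
    list(scan = scan, max_pos = side$max_pos, max_lrt = side$max_lrt,
         threshold = null_to_na(side$threshold),
         ci = c(side$ci_low, side$ci_high),
         effect = null_to_na(side$effect),
         effect_sd = null_to_na(side$effect_sd), n = side$n,
         model = side$model, fixed_pos = null_to_na(side$fixed_pos)),
    class = "qtl_scan"
  )
  out
}

null_to_na <- function(x) if (is.null(x)) NA_real_ else x

#' Check that two tables cover the same animals
#'
#' @param ... Named data frames, each with an `animal` column.
#' @return Invisibly `TRUE`; errors naming the offending animals otherwise.
#' @export
check_animal_consistency <- function(...) {
  tables <- list(...)
  stopifnot(length(tables) >= 2, !is.null(names(tables)))
  ref <- tables[[1L]]$animal
  for (nm in names(tables)[-1L]) {
    other <- tables[[nm]]$animal
    extra <- setdiff(other, ref)
    missing <- setdiff(ref, other)
    if (length(extra) + length(missing) > 0) {
      stop(sprintf(
        "animal sets differ between '%s' and '%s'%s%s",
        names(tables)[1L], nm,
        if (length(missing)) paste0("; missing: ",
                                    paste(utils::head(missing, 5),
                                          collapse = ", ")) else "",
        if (length(extra)) paste0("; unexpected: ",
                                  paste(utils::head(extra, 5),
                                        collapse = ", ")) else ""),
        call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a simulated study to a directory
#'
#' @param sim A [simulate_family()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "halfsib_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_marker_map(sim$map, file.path(dir, "map.tsv"))
  write_inheritance(sim$inherit, file.path(dir, "inherit.tsv"))
  write_phenotypes(sim$pheno, file.path(dir, "pheno.tsv"))
  write_expression(sim$expr, file.path(dir, "expr.tsv"))
  truth <- list(
    positions = sim$truth$positions,
    origin = sim$truth$origin,
    trait_gene_ids = sim$truth$trait_gene_ids,
    interacting_gene_ids = sim$truth$interacting_gene_ids,
    sire_phase = as.list(sim$truth$sire_phase)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
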