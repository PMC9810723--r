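#' Gene sets and their input/output
#'
#' A gene set is an ordered collection of unique gene identifiers with a
#' species tag and free-text provenance.  Instances of this type carry the
#' NF-kB target-gene lists (assembled from a CD34+ stem-cell transcription
#' factor network plus curated compilations) whose activity the scoring
#' module estimates, as well as derived single-cell signatures.
#'
#' @param name Set name (single string).
#' @param genes Character vector of gene identifiers; duplicates are dropped
#'   (first occurrence kept) with a warning, order preserved.
#' @param species `"human"`, `"mouse"` or `"other"`.
#' @param provenance Free-text origin note.
#' @return An object of class `gene_set`.
#' @examples
#' gene_set("NFKB_TARGETS", c("NFKBIA", "TNF", "IL1RN"), species = "human")
#' @export
gene_set <- function(name, genes, species = c("human", "mouse", "other"),
                     provenance = "") {
  species <- match.arg(species)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_plagekit("gene set must be nonempty")
  if (anyDuplicated(genes)) {
    warning(sprintf("dropping %d duplicated gene(s) in set '%s'",
                    sum(duplicated(genes)), name), call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, species = species, genes = genes,
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d genes\n", x$name, x$species,
              length(x$genes)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from GMT or two-column TSV
#'
#' GMT is the standard tab-separated layout: set name, description, then one
#' gene per field.  The TSV dialect has two columns, `set_name` and `gene`,
#' one gene per row (no header).  Duplicate genes within a set are dropped
#' with a warning; a set with no genes is an error that names the offending
#' line.
#'
#' @param path File path.
#' @param format `"gmt"` or `"tsv"`.
#' @param species Species tag attached to every returned set.
#' @return A list of [gene_set()] objects, in file order.
#' @export
read_gene_sets <- function(path, format = c("gmt", "tsv"),
                           species = c("human", "mouse", "other")) {
  format <- match.arg(format)
  species <- match.arg(species)
  if (!file.exists(path)) stop_plagekit(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_plagekit("no gene sets in file")
  if (format == "gmt") {
    sets <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 2L) {
        stop_plagekit(sprintf("malformed GMT line %d (need name, description, genes)", i))
      }
      genes <- fields[-(1:2)]
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0L) {
        stop_plagekit(sprintf("empty gene set at line %d ('%s')", i, fields[[1L]]))
      }
      sets[[i]] <- gene_set(fields[[1L]], genes, species = species,
                            provenance = fields[[2L]])
    }
    sets
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad)) {
      stop_plagekit(sprintf("malformed TSV line %d (need set_name<TAB>gene)", bad[[1L]]))
    }
    set_names <- vapply(parts, `[[`, "", 1L)
    genes <- vapply(parts, `[[`, "", 2L)
    lapply(unique(set_names), function(nm) {
      gene_set(nm, genes[set_names == nm], species = species,
               provenance = basename(path))
    })
  }
}

#' Write gene sets to GMT or two-column TSV
#'
#' Inverse of [read_gene_sets()]: `read_gene_sets(write_gene_sets(x))`
#' round-trips gene content exactly.
#'
#' @param sets A list of [gene_set()] objects (or a single one).
#' @param path Output path.
#' @param format `"gmt"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- if (format == "gmt") {
    vapply(sets, function(s) {
      paste(c(s$name, if (nzchar(s$provenance)) s$provenance else "na",
              s$genes), collapse = "\t")
    }, "")
  } else {
    unlist(lapply(sets, function(s) paste(s$name, s$genes, sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Ortholog mapping tables
#'
#' A snapshot of source-to-target gene homology pairs (for example a human
#' to mouse table exported from a comparative-genomics database).  Tables
#' are user-supplied files, never fetched live, because mapped set sizes
#' depend on the database version.
#'
#' @param pairs Data frame with columns `source_gene`, `target_gene` and
#'   optionally `homology_type` (pairs whose type is not
#'   `"ortholog_one2one"` are never used in one-to-one mode even if they are
#'   structurally unique).
#' @param source_species,target_species Species tags.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(pairs, source_species = c("human", "mouse", "other"),
                         target_species = c("mouse", "human", "other")) {
  source_species <- match.arg(source_species)
  target_species <- match.arg(target_species)
  pairs <- as.data.frame(pairs)
  for (col in c("source_gene", "target_gene")) {
    if (is.null(pairs[[col]])) {
      stop_plagekit(sprintf("`pairs` must contain a `%s` column", col))
    }
    pairs[[col]] <- as.character(pairs[[col]])
  }
  pairs <- unique(pairs)
  structure(list(pairs = pairs, source_species = source_species,
                 target_species = target_species),
            class = "ortholog_map")
}

#' @param path TSV with columns `source_gene`, `target_gene` and optionally
#'   `homology_type` (header required).
#' @rdname ortholog_map
#' @export
read_ortholog_map <- function(path,
                              source_species = c("human", "mouse", "other"),
                              target_species = c("mouse", "human", "other")) {
  ortholog_map(utils::read.delim(path), source_species, target_species)
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map %s -> %s: %d pairs\n", x$source_species,
              x$target_species, nrow(x$pairs)))
  invisible(x)
}

#' Map a gene set across species through an ortholog table
#'
#' In `one2one_only` mode (the default, matching the reciprocal-unique
#' homology convention) a source gene is mapped only when it has exactly one
#' target and that target has exactly one source; genes with zero or
#' multiple targets are dropped.  A mapping report
#' (`n input, n mapped, n dropped`) is appended to the output provenance.
#'
#' @param set A [gene_set()] whose species matches the map's source species.
#' @param map An [ortholog_map()].
#' @param mode `"one2one_only"` or `"all"` (every target of every source
#'   gene, deduplicated).
#' @return A [gene_set()] in the target species.  An empty mapped set is an
#'   error.
#' @export
map_orthologs <- function(set, map, mode = c("one2one_only", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "gene_set"), inherits(map, "ortholog_map"))
  if (set$species != map$source_species) {
    stop_plagekit(sprintf("species mismatch: set is %s but map source is %s",
                          set$species, map$source_species))
  }
  pairs <- map$pairs
  if (mode == "one2one_only") {
    if (!is.null(pairs$homology_type)) {
      pairs <- pairs[pairs$homology_type == "ortholog_one2one", , drop = FALSE]
    }
    src_multi <- names(which(table(pairs$source_gene) > 1L))
    tgt_multi <- names(which(table(pairs$target_gene) > 1L))
    pairs <- pairs[!(pairs$source_gene %in% src_multi) &
                     !(pairs$target_gene %in% tgt_multi), , drop = FALSE]
  }
  hit <- pairs[pairs$source_gene %in% set$genes, , drop = FALSE]
  # preserve the input set's gene order
  hit <- hit[order(match(hit$source_gene, set$genes)), , drop = FALSE]
  mapped <- unique(hit$target_gene)
  n_in <- length(set$genes)
  n_mapped <- length(unique(hit$source_gene))
  report <- sprintf("mapped %s->%s: %d input, %d mapped, %d dropped",
                    map$source_species, map$target_species,
                    n_in, n_mapped, n_in - n_mapped)
  if (length(mapped) == 0L) {
    stop_plagekit(sprintf("empty after mapping (%s)", report))
  }
  gene_set(set$name, mapped, species = map$target_species,
           provenance = paste(c(set$provenance, report)[nzchar(c(set$provenance, report))],
                              collapse = "; "))
}

#' Restrict a gene set to a measured gene universe
#'
#' Used before any scoring step so that only genes present in the expression
#' matrix at hand contribute; mirrors the requirement that signature genes
#' be present in the dataset.
#'
#' @param set A [gene_set()].
#' @param universe Character vector of measured gene identifiers.
#' @return A [gene_set()] with genes restricted to `universe` (input order
#'   preserved); an empty intersection is an error because downstream scores
#'   are undefined.
#' @export
intersect_with_universe <- function(set, universe) {
  stopifnot(inherits(set, "gene_set"))
  universe <- as.character(universe)
  if (length(universe) == 0L) stop_plagekit("`universe` must be nonempty")
  kept <- set$genes[set$genes %in% universe]
  if (length(kept) == 0L) {
    stop_plagekit(sprintf("gene set '%s' has no genes in the universe", set$name))
  }
  out <- set
  out$genes <- kept
  out$provenance <- paste(
    c(set$provenance,
      sprintf("restricted to universe: %d of %d retained",
              length(kept), length(set$genes)))[
        nzchar(c(set$provenance, "x"))],
    collapse = "; ")
  out
}
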