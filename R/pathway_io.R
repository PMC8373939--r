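#' Read a gene-set collection from a GMT file
#'
#' Parses the tab-separated GMT format (one gene set per line: identifier,
#' description, then member genes). Duplicate gene ids within a line are
#' removed with a warning; duplicate pathway ids across lines are an error.
#' Gene identifiers are whitespace-stripped and matched case-sensitively;
#' no symbol/ID translation is attempted.
#'
#' @param path Path to a GMT file (UTF-8, LF or CRLF line endings).
#' @return A `pathway_collection` object: a list with components `sets`
#'   (named list of gene sets, each with `id`, `name`, `genes`, `size_raw`,
#'   `size_effective`), `category_of` (named list mapping pathway id to
#'   category labels; empty until [read_hierarchy_map()] output is attached
#'   via [set_categories()]), `categories` (character vector) and
#'   `n_dropped` (sets removed by [restrict_to_universe()]).
#' @seealso [read_hierarchy_map()], [restrict_to_universe()], [write_gmt()]
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("P1\tfirst\tg1\tg2\tg3", "P2\tsecond\tg2\tg4"), gmt)
#' col <- read_gmt(gmt)
#' length(col$sets)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, " (fewer than 3 tab-separated fields): ",
           path)
    }
    genes <- fields[-c(1, 2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene ids in set '", fields[[1]], "' (line ", i,
              ") deduplicated", call. = FALSE)
      genes <- unique(genes)
    }
    ids[[i]] <- fields[[1]]
    sets[[i]] <- list(id = fields[[1]], name = fields[[2]], genes = genes,
                      size_raw = length(genes), size_effective = NA_integer_)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sets) <- ids
  structure(list(sets = sets, category_of = list(),
                 categories = character(0), n_dropped = 0L),
            class = "pathway_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `pathway_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$id, s$name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway-to-category hierarchy map
#'
#' Reads a headerless two-column TSV (pathway id, top-level category label).
#' A pathway id may appear on several rows; it then belongs to every listed
#' category (multi-parentage, as in the Reactome hierarchy). Categories are
#' collected in file order.
#'
#' @param path Path to the two-column TSV.
#' @return A named list mapping pathway id to a character vector of category
#'   labels, with attribute `"categories"` giving distinct labels in file
#'   order.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("P1\tImmune System", "P2\tCell Cycle", "P1\tDisease"), tsv)
#' map <- read_hierarchy_map(tsv)
#' map[["P1"]]
#' @export
read_hierarchy_map <- function(path) {
  if (!file.exists(path)) stop("hierarchy map not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("hierarchy map is empty: ", path)
  map <- list()
  cats <- character(0)
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(fields) != 2 || !all(nzchar(fields))) {
      stop("malformed hierarchy map line ", i,
           " (expected 2 non-empty tab-separated columns): ", path)
    }
    id <- fields[[1]]; lab <- fields[[2]]
    map[[id]] <- unique(c(map[[id]], lab))
    if (!(lab %in% cats)) cats <- c(cats, lab)
  }
  attr(map, "categories") <- cats
  map
}

#' Attach a hierarchy map to a pathway collection
#'
#' Pathways absent from the map are assigned to the reserved category
#' `"Uncategorized"` so that scoring stays total; they can be excluded from
#' aggregation downstream. Map entries whose pathway id is not in the
#' collection are dropped with a warning.
#'
#' @param collection A `pathway_collection`.
#' @param map Output of [read_hierarchy_map()] (or an equivalent named list).
#' @return The collection with `category_of` and `categories` filled in.
#' @export
set_categories <- function(collection, map) {
  stopifnot(inherits(collection, "pathway_collection"))
  ids <- names(collection$sets)
  unknown <- setdiff(names(map), ids)
  if (length(unknown) > 0) {
    warning(length(unknown),
            " hierarchy-map entries not in the collection were ignored",
            call. = FALSE)
  }
  category_of <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    labs <- map[[id]]
    category_of[[id]] <- if (is.null(labs)) "Uncategorized" else labs
  }
  cats <- attr(map, "categories")
  if (is.null(cats)) cats <- unique(unlist(map, use.names = FALSE))
  cats <- cats[cats %in% unique(unlist(category_of, use.names = FALSE))]
  if (any(vapply(category_of, function(x) "Uncategorized" %in% x, logical(1))))
    cats <- c(cats, "Uncategorized")
  collection$category_of <- category_of
  collection$categories <- cats
  collection
}

#' Restrict a pathway collection to a gene universe
#'
#' Intersects every set with the profiled gene universe (the genes of the
#' ranked list), records the effective size Ng, and drops sets smaller than
#' `min_size`. A one-gene set carries weight log2(1) = 0 in the size-weighting
#' step and a degenerate running sum, so the default `min_size` is 2.
#'
#' @param collection A `pathway_collection`.
#' @param universe Character vector of gene ids present in the ranked list.
#' @param min_size Minimum effective size to keep a set (default 2).
#' @param quiet Suppress the dropped-set message.
#' @return The restricted collection; `n_dropped` counts removed sets, and
#'   each kept set has `size_effective = |genes  intersect  universe|`.
#' @export
restrict_to_universe <- function(collection, universe, min_size = 2,
                                 quiet = FALSE) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  keep <- logical(length(collection$sets))
  for (i in seq_along(collection$sets)) {
    s <- collection$sets[[i]]
    s$genes <- s$genes[s$genes %in% universe]
    s$size_effective <- length(s$genes)
    collection$sets[[i]] <- s
    keep[[i]] <- s$size_effective >= min_size
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    .msg("restrict_to_universe: dropped ", n_drop, " set(s) with fewer than ",
         min_size, " genes in the universe", quiet = quiet)
  }
  collection$sets <- collection$sets[keep]
  if (length(collection$category_of) > 0) {
    collection$category_of <-
      collection$category_of[names(collection$sets)]
    collection$categories <- collection$categories[
      collection$categories %in%
        unique(unlist(collection$category_of, use.names = FALSE))]
  }
  collection$n_dropped <- collection$n_dropped + n_drop
  collection
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("Pathway collection:", length(x$sets), "gene sets")
  if (length(x$categories) > 0)
    cat(",", length(x$categories), "categories")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\n")
  sz <- vapply(x$sets, function(s) s$size_raw, integer(1))
  if (length(sz) > 0)
    cat("  set sizes (raw): min ", min(sz), ", median ",
        stats::median(sz), ", max ", max(sz), "\n", sep = "")
  invisible(x)
}
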