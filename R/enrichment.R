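# Hypergeometric over-representation analysis against GMT gene-set
# collections, with the set-size window and BH control used for GO-term
# screening of EV signatures.

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (tab-separated: name, description,
#'   members...).
#' @return A list of class `"gene_set_collection"`: `sets` (named list of
#'   character vectors, duplicates within a set removed) and `descriptions`
#'   (named character).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s.",
                  paste(head(short, 5), collapse = ", ")),
          class = "evcargo_parse_error")
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort("Duplicate set names in GMT.", class = "evcargo_parse_error")
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  desc <- setNames(vapply(parts, `[[`, character(1), 2), nm)
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, median size %s\n",
              length(x$sets),
              median(vapply(x$sets, length, integer(1)))))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query within a
#' background universe using the upper hypergeometric tail
#' `p = P(X >= k)`. Set sizes are measured after intersecting each set with
#' the universe; sets outside `[min_size, max_size]` are excluded before
#' testing, and BH adjustment runs across the tested sets only.
#'
#' @param query Character vector of genes (violations of
#'   `query %in% universe` are dropped with a warning).
#' @param collection A `gene_set_collection` from [read_gmt()], or a named
#'   list of character vectors.
#' @param universe Background gene list (all detected genes).
#' @param min_size,max_size Tested set-size window within the universe
#'   (defaults 15 and 500).
#' @param p_cut,q_cut Significance thresholds applied to the `significant`
#'   flag (defaults 0.05 and 0.20).
#'
#' @return A tibble of class `"ora_result"`: `term`, `description`,
#'   `set_size`, `query_size`, `overlap`, `p_value`, `q_value`, `members`
#'   (list column), `significant`; sorted by p-value.
#' @export
ora <- function(query, collection, universe, min_size = 15, max_size = 500,
                p_cut = 0.05, q_cut = 0.20) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  desc <- if (inherits(collection, "gene_set_collection"))
    collection$descriptions else setNames(rep(NA_character_, length(sets)),
                                          names(sets))
  universe <- unique(universe)
  if (!length(universe)) abort("Empty universe.",
                               class = "evcargo_input_error")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe dropped.",
                 length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n_query <- length(query)

  rows <- purrr::imap(sets, function(members, nm) {
    set_u <- intersect(members, universe)
    K <- length(set_u)
    if (K < min_size || K > max_size) return(NULL)
    hit <- intersect(query, set_u)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n_query, lower.tail = FALSE)
    tibble::tibble(term = nm, description = desc[[nm]] %||% NA_character_,
                   set_size = K, query_size = n_query, overlap = k,
                   p_value = p, members = list(sort(hit)))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) {
    out <- tibble::tibble(term = character(), description = character(),
                          set_size = integer(), query_size = integer(),
                          overlap = integer(), p_value = numeric(),
                          members = list(), q_value = numeric(),
                          significant = logical())
    class(out) <- c("ora_result", class(out))
    return(out)
  }
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$p_value < p_cut & out$q_value < q_cut
  out <- dplyr::arrange(out, .data$p_value, .data$term) |>
    dplyr::relocate("members", .after = "significant")
  class(out) <- c("ora_result", class(out))
  out
}
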