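#' Construct a typed herb--symptom knowledge graph
#'
#' A knowledge graph holds five entity types -- symptom (`SY`), herb (`HB`),
#' efficacy (`EF`), property (`PP`) and meridian (`MD`) -- joined by five
#' undirected relation types (`HB-SY`, `SY-SY`, `HB-EF`, `HB-PP`, `HB-MD`).
#' Relations are deduplicated per unordered endpoint pair and relation type,
#' self-loops are rejected, and every entity must carry a single consistent
#' type across all relations it appears in.
#'
#' For a heterotyped relation such as `HB-SY` the first column is taken to be
#' the first-named type (the herb) and the second column the second-named
#' type (the symptom). Homotyped `SY-SY` rows are stored with endpoints in
#' sorted order.
#'
#' @param relations A data frame with columns `u`, `v`, `rtype`.
#' @return A `knowledge_graph`: a list with tibbles `entities` (`id`,
#'   `etype`) and `relations` (`u`, `v`, `rtype`).
#' @examples
#' kg <- knowledge_graph(tibble::tibble(
#'   u = c("ginseng", "ginseng"), v = c("fatigue", "tonify qi"),
#'   rtype = c("HB-SY", "HB-EF")
#' ))
#' kg_summary(kg)
#' @export
knowledge_graph <- function(relations = NULL) {
  if (is.null(relations) || nrow(relations) == 0L) {
    return(new_knowledge_graph(
      entities = tibble(id = character(), etype = character()),
      relations = tibble(u = character(), v = character(), rtype = character())
    ))
  }
  relations <- as_tibble(relations)[, c("u", "v", "rtype")]
  relations$u <- as.character(relations$u)
  relations$v <- as.character(relations$v)
  relations$rtype <- as.character(relations$rtype)

  bad <- !relations$rtype %in% RTYPES
  if (any(bad)) {
    abort(sprintf("unknown relation type(s): %s",
                  paste(unique(relations$rtype[bad]), collapse = ", ")))
  }
  if (any(relations$u == relations$v)) {
    abort("self-loop relations are not allowed")
  }

  # canonical endpoint order: homotyped edges sorted lexicographically
  homo <- relations$rtype == "SY-SY"
  flip <- homo & relations$u > relations$v
  if (any(flip)) {
    tmp <- relations$u[flip]
    relations$u[flip] <- relations$v[flip]
    relations$v[flip] <- tmp
  }
  relations <- dplyr::distinct(relations)

  types_u <- vapply(relations$rtype, function(r) rtype_endpoints(r)[1], "",
                    USE.NAMES = FALSE)
  types_v <- vapply(relations$rtype, function(r) rtype_endpoints(r)[2], "",
                    USE.NAMES = FALSE)
  ent <- tibble(
    id = c(relations$u, relations$v),
    etype = c(types_u, types_v)
  )
  ent <- dplyr::distinct(ent)
  dup <- ent$id[duplicated(ent$id)]
  if (length(dup)) {
    abort(sprintf("entity typed inconsistently across relations: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  ent <- ent[order(match(ent$etype, ETYPES), ent$id), ]
  relations <- relations[order(match(relations$rtype, RTYPES),
                               relations$u, relations$v), ]
  new_knowledge_graph(entities = ent, relations = relations)
}

new_knowledge_graph <- function(entities, relations) {
  structure(list(entities = entities, relations = relations),
            class = "knowledge_graph")
}

#' Read a knowledge graph from tab-separated edge lists
#'
#' Each file is a 3-column TSV `u<TAB>v<TAB>rtype`; lines starting with `#`
#' and an optional `u  v  rtype` header are skipped. Duplicate rows collapse
#' silently. A per-type summary is logged via [message()].
#'
#' @param edge_files Character vector of file paths.
#' @return A [knowledge_graph()].
#' @export
load_kg <- function(edge_files) {
  rows <- purrr::map(edge_files, function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- which(keep)
    if (!length(lines)) {
      return(tibble(u = character(), v = character(), rtype = character()))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    arity <- lengths(parts)
    if (any(arity != 3L)) {
      i <- which(arity != 3L)[1]
      abort(sprintf("malformed row in %s at line %d: expected 3 tab-separated fields, got %d",
                    path, lineno[i], arity[i]))
    }
    m <- do.call(rbind, parts)
    out <- tibble(u = m[, 1], v = m[, 2], rtype = m[, 3])
    if (identical(tolower(out$u[1]), "u") && identical(tolower(out$v[1]), "v")) {
      out <- out[-1, ]
    }
    bad <- !out$rtype %in% RTYPES
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("unknown relation type '%s' in %s", out$rtype[i], path))
    }
    out
  })
  kg <- knowledge_graph(dplyr::bind_rows(rows))
  s <- kg_summary(kg)
  inform(sprintf(
    "loaded knowledge graph: %d entities (%s); %d relations (%s)",
    sum(s$entities$count),
    paste(sprintf("%s %d", s$entities$etype, s$entities$count), collapse = ", "),
    sum(s$relations$count),
    paste(sprintf("%s %d", s$relations$rtype, s$relations$count), collapse = ", ")
  ))
  kg
}

#' Summarize entity and relation counts of a knowledge graph
#'
#' @param kg A [knowledge_graph()].
#' @return A list of two tibbles: `entities` (`etype`, `count`) in the order
#'   SY, HB, EF, PP, MD and `relations` (`rtype`, `count`) in the order
#'   HB-SY, SY-SY, HB-EF, HB-PP, HB-MD.
#' @export
kg_summary <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  ent <- tibble(
    etype = ETYPES,
    count = vapply(ETYPES, function(t) sum(kg$entities$etype == t), 0L,
                   USE.NAMES = FALSE)
  )
  rel <- tibble(
    rtype = RTYPES,
    count = vapply(RTYPES, function(t) sum(kg$relations$rtype == t), 0L,
                   USE.NAMES = FALSE)
  )
  list(entities = ent, relations = rel)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  s <- kg_summary(x)
  cat(sprintf("<knowledge_graph> %d entities, %d relations\n",
              sum(s$entities$count), sum(s$relations$count)))
  cat("entities: ", paste(sprintf("%s=%d", s$entities$etype, s$entities$count),
                          collapse = " "), "\n")
  cat("relations:", paste(sprintf("%s=%d", s$relations$rtype, s$relations$count),
                          collapse = " "), "\n")
  invisible(x)
}

#' Accessors for typed slices of a knowledge graph
#'
#' @param kg A [knowledge_graph()].
#' @param etype,rtype An entity / relation type code.
#' @return `kg_entity_ids()`: sorted character vector of entity ids;
#'   `kg_edges()`: two-column tibble (`u`, `v`) of that relation type.
#' @export
kg_entity_ids <- function(kg, etype) {
  sort(kg$entities$id[kg$entities$etype == etype])
}

#' @rdname kg_entity_ids
#' @export
kg_edges <- function(kg, rtype) {
  kg$relations[kg$relations$rtype == rtype, c("u", "v")]
}

#' Write a knowledge graph to per-relation-type TSV files
#'
#' @param kg A [knowledge_graph()].
#' @param dir Output directory; one `<rtype>.tsv` file per relation type
#'   present.
#' @return Invisibly, the paths written.
#' @export
save_kg <- function(kg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (rt in unique(kg$relations$rtype)) {
    e <- kg$relations[kg$relations$rtype == rt, ]
    path <- file.path(dir, paste0(gsub("-", "_", rt), ".tsv"))
    writeLines(sprintf("%s\t%s\t%s", e$u, e$v, e$rtype), path, useBytes = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
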