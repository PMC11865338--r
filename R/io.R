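#' Read a disturbance evidence table
#'
#' Parses a long-format delimited table with one row per documented
#' microbial disturbance: a source identifier, the entity (a dietary
#' fiber or a disease) it concerns, the microbe, the taxonomic rank at
#' which the change was reported, and the direction of change
#' (increase or decrease in relative abundance versus the healthy /
#' habitual-diet baseline). Rows with an unrecognized rank or direction
#' token are rejected and collected in the \code{rejected} attribute,
#' never silently dropped: \code{nrow(parsed) + nrow(rejected)} equals
#' the input row count.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter, tab by default.
#' @param col_map Named list mapping the canonical column roles
#'   (\code{source_id}, \code{entity_type}, \code{entity_name},
#'   \code{microbe_name}, \code{rank}, \code{direction},
#'   \code{body_site}, \code{notes}) to the column names used in the
#'   file. Only roles present in the list are remapped;
#'   \code{body_site} and \code{notes} are optional columns.
#' @return A \code{data.frame} of class \code{bhwa_evidence} with
#'   columns \code{source_id}, \code{entity_type}, \code{entity_name},
#'   \code{microbe_name}, \code{rank}, \code{direction} (integer +1 /
#'   -1), \code{body_site}, \code{notes}; rejected rows (with a
#'   \code{reason} column) are attached as \code{attr(x, "rejected")}.
#' @export
read_evidence <- function(path, delim = "\t", col_map = list()) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  defaults <- c(source_id = "source_id", entity_type = "entity_type",
                entity_name = "entity_name", microbe_name = "microbe_name",
                rank = "rank", direction = "direction",
                body_site = "body_site", notes = "notes")
  cols <- defaults
  for (role in names(col_map)) cols[[role]] <- col_map[[role]]

  mandatory <- c("source_id", "entity_type", "entity_name",
                 "microbe_name", "rank", "direction")
  missing <- setdiff(unname(cols[mandatory]), names(raw))
  if (length(missing) > 0)
    stop("evidence table missing mandatory column(s): ",
         paste(missing, collapse = ", "))

  get_col <- function(role) {
    nm <- cols[[role]]
    if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  }
  df <- data.frame(
    source_id    = norm_display(get_col("source_id")),
    entity_type  = tolower(norm_display(get_col("entity_type"))),
    entity_name  = norm_display(get_col("entity_name")),
    microbe_name = norm_display(get_col("microbe_name")),
    rank         = tolower(norm_display(get_col("rank"))),
    direction_token = tolower(norm_display(get_col("direction"))),
    body_site    = norm_display(get_col("body_site")),
    notes        = get_col("notes"),
    stringsAsFactors = FALSE
  )
  df$body_site[df$body_site == "" | is.na(df$body_site)] <- NA_character_

  dir_map <- c(increase = 1L, decrease = -1L, "+1" = 1L, "-1" = -1L,
               "1" = 1L, up = 1L, down = -1L)
  df$direction <- unname(dir_map[df$direction_token])

  reason <- rep(NA_character_, nrow(df))
  reason[!(df$rank %in% taxonomic_ranks())] <- "unsupported rank"
  bad_dir <- is.na(df$direction)
  reason[bad_dir & is.na(reason)] <- "unrecognized direction"
  reason[df$entity_name == "" & is.na(reason)] <- "empty entity name"
  reason[df$microbe_name == "" & is.na(reason)] <- "empty microbe name"
  bad_type <- !(df$entity_type %in% c("fiber", "disease"))
  reason[bad_type & is.na(reason)] <- "unknown entity type"

  ok <- is.na(reason)
  rejected <- df[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  out <- df[ok, c("source_id", "entity_type", "entity_name",
                  "microbe_name", "rank", "direction", "body_site",
                  "notes")]
  rownames(out) <- NULL
  rownames(rejected) <- NULL
  if (nrow(out) == 0) stop("no valid evidence rows after parsing")
  attr(out, "rejected") <- rejected
  class(out) <- c("bhwa_evidence", "data.frame")
  out
}

#' Construct an evidence table from a data frame
#'
#' Convenience constructor applying the same validation as
#' \code{\link{read_evidence}} to an in-memory data frame.
#'
#' @param df Data frame with the canonical evidence columns.
#' @return A validated \code{bhwa_evidence} data frame.
#' @export
as_evidence <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  read_evidence(tmp)
}

gg_prefixes <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                 f = "family", g = "genus", s = "species")

parse_gg_string <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  pre <- sub("__.*$", "", parts)
  if (any(!grepl("^[a-z]__", parts)) || any(!pre %in% names(gg_prefixes)))
    stop("malformed lineage string: ", s)
  vals <- sub("^[a-z]__", "", parts)
  names(vals) <- unname(gg_prefixes[pre])
  vals <- vals[vals != ""]
  vals <- vals[names(vals) %in% taxonomic_ranks()]  # kingdom ignored
  vals
}

#' Read a taxonomy lineage table
#'
#' Maps microbe names to their six-rank lineage (species, genus,
#' family, order, class, phylum). Two layouts are supported:
#' \describe{
#'   \item{\code{greengenes_string}}{a \code{lineage} column holding
#'     rank-prefixed strings of the form
#'     \code{"k__...;p__...;c__...;o__...;f__...;g__...;s__..."}. The
#'     deepest non-empty slot defines the taxon itself; empty slots
#'     yield absent lineage entries; the kingdom prefix is ignored.}
#'   \item{\code{rank_columns}}{explicit columns \code{taxon_name},
#'     \code{rank}, plus one column per rank holding the ancestor names
#'     (blank or absent where unknown).}
#' }
#' Exact duplicate records are deduplicated; two records giving the
#' same taxon conflicting lineages are an error naming the taxon.
#'
#' @param path Path to a delimited text file with a header row.
#' @param format One of \code{"auto"} (default: greengenes when the
#'   file has a \code{lineage} column, rank columns otherwise),
#'   \code{"greengenes_string"}, \code{"rank_columns"}.
#' @param delim Field delimiter, tab by default.
#' @return A \code{data.frame} of class \code{bhwa_taxonomy} with
#'   columns \code{taxon_name}, \code{rank}, and one column per rank
#'   holding ancestor names (\code{NA} where absent; the taxon's own
#'   rank column holds its own name).
#' @export
read_taxonomy <- function(path,
                          format = c("auto", "greengenes_string",
                                     "rank_columns"),
                          delim = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  ranks <- taxonomic_ranks()
  if (format == "auto")
    format <- if ("lineage" %in% names(raw)) "greengenes_string"
              else "rank_columns"

  if (format == "greengenes_string") {
    if (!"lineage" %in% names(raw))
      stop("greengenes_string format requires a 'lineage' column")
    recs <- lapply(raw$lineage, function(s) {
      vals <- parse_gg_string(s)
      if (length(vals) == 0) return(NULL)
      # deepest (lowest) non-empty rank names the taxon itself
      own <- ranks[min(match(names(vals), ranks))]
      row <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
      row[names(vals)] <- norm_display(vals)
      list(taxon_name = row[[own]], rank = own, lineage = row)
    })
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (length(recs) == 0) stop("no parseable lineage rows")
    tab <- data.frame(
      taxon_name = vapply(recs, `[[`, character(1), "taxon_name"),
      rank = vapply(recs, `[[`, character(1), "rank"),
      stringsAsFactors = FALSE
    )
    for (r in ranks)
      tab[[r]] <- vapply(recs, function(x) x$lineage[[r]], character(1))
  } else {
    need <- c("taxon_name", "rank")
    if (!all(need %in% names(raw)))
      stop("rank_columns format requires columns: ",
           paste(need, collapse = ", "))
    tab <- data.frame(taxon_name = norm_display(raw$taxon_name),
                      rank = tolower(norm_display(raw$rank)),
                      stringsAsFactors = FALSE)
    if (any(!tab$rank %in% ranks))
      stop("unsupported rank in taxonomy: ",
           paste(unique(tab$rank[!tab$rank %in% ranks]), collapse = ", "))
    for (r in ranks) {
      v <- if (r %in% names(raw)) norm_display(raw[[r]])
           else rep(NA_character_, nrow(raw))
      v[v == "" | v == "NA"] <- NA_character_
      tab[[r]] <- v
    }
    # own-rank slot always names the taxon itself
    for (i in seq_len(nrow(tab))) tab[i, tab$rank[i]] <- tab$taxon_name[i]
  }

  # a lineage must never assign a name at a rank below the taxon's own
  for (i in seq_len(nrow(tab))) {
    own_i <- match(tab$rank[i], ranks)
    below <- ranks[seq_len(own_i - 1L)]
    if (own_i > 1 && any(!is.na(unlist(tab[i, below]))))
      stop("lineage assigns a rank below the taxon's own rank for: ",
           tab$taxon_name[i])
  }

  # deduplicate; conflicting lineages for one taxon are an error
  key <- paste(norm_key(tab$taxon_name), tab$rank)
  full <- apply(tab[, ranks], 1L, function(x)
    paste(ifelse(is.na(x), "", norm_key(x)), collapse = "|"))
  keep <- !duplicated(key)
  for (k in unique(key[duplicated(key)])) {
    if (length(unique(full[key == k])) > 1)
      stop("conflicting lineages for taxon: ",
           tab$taxon_name[which(key == k)[1]])
  }
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("bhwa_taxonomy", "data.frame")
  tab
}

#' Write and read result tables
#'
#' Similarity tables, edge lists, loop-census reports, disturbance
#' score tables and cluster assignments are all plain long-format TSV;
#' numeric columns are written with 15 significant digits so a
#' write/read round trip preserves values to at least 12 significant
#' digits. Dendrograms are written as Newick via
#' \code{\link{write_dendrogram}}.
#'
#' @param table A data frame (any of the pipeline's result tables).
#' @param path Output file path.
#' @param delim Field delimiter, tab by default.
#' @return Invisibly, the path written.
#' @export
write_results <- function(table, path, delim = "\t") {
  if (is.null(table) || nrow(table) == 0) stop("refusing to write empty table")
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) {
    if (!is.integer(out[[j]])) out[[j]] <- signif(out[[j]], 15)
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, delim = "\t") {
  utils::read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    quote = "", comment.char = "")
}

#' Export a signed network
#'
#' Writes the edge list as TSV (\code{node_i}, \code{node_j},
#' \code{sign} encoded \code{"+"}/\code{"-"}, \code{similarity},
#' \code{fdr}) and, optionally, a JSON document
#' \code{\{nodes:[\{id\}], edges:[\{source,target,sim,fdr,sign\}]\}}
#' suitable for web display.
#'
#' @param network A \code{signed_network} from
#'   \code{\link{build_network}}.
#' @param path Output TSV path.
#' @param json_path Optional JSON output path.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(network, path, json_path = NULL) {
  stopifnot(inherits(network, "signed_network"))
  e <- network$edges
  tab <- data.frame(node_i = e$node_i, node_j = e$node_j,
                    sign = ifelse(e$sign > 0, "+", "-"),
                    similarity = e$similarity, fdr = e$fdr,
                    stringsAsFactors = FALSE)
  write_results(tab, path)
  if (!is.null(json_path)) {
    doc <- list(
      nodes = lapply(network$nodes, function(n) list(id = n)),
      edges = lapply(seq_len(nrow(e)), function(i)
        list(source = e$node_i[i], target = e$node_j[i],
             sim = e$similarity[i], fdr = e$fdr[i],
             sign = ifelse(e$sign[i] > 0, "+", "-")))
    )
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a dendrogram as Newick
#'
#' @param assignment A \code{cluster_assignment} from
#'   \code{\link{cluster_entities}}.
#' @param path Output file path (Newick).
#' @return Invisibly, the Newick string written.
#' @export
write_dendrogram <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  phy <- ape::as.phylo(assignment$hclust)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
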