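norm_gene_id <- function(x) toupper(trimws(x))

#' Read a gene annotation table
#'
#' TSV with columns \code{gene_id}, \code{is_membrane} (TRUE/FALSE, 1/0,
#' yes/no) and \code{drugs} (semicolon-separated drug names, possibly
#' empty). Gene ids are uppercased and whitespace-trimmed; malformed rows
#' raise a line-numbered parse error.
#'
#' @param path Path to the annotation TSV.
#' @return An \code{annotation_table}: data.frame with \code{gene_id},
#'   \code{is_membrane} (logical) and \code{drugs} (list column of
#'   character vectors).
#' @export
read_annotation_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "is_membrane", "drugs")
  if (!all(need %in% names(raw)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  parse_flag <- function(v, i) {
    s <- tolower(trimws(v))
    if (s %in% c("true", "1", "yes")) return(TRUE)
    if (s %in% c("false", "0", "no", "")) return(FALSE)
    stop(sprintf("annotation parse error at line %d: bad is_membrane value '%s'",
                 i + 1L, v))
  }
  ids <- norm_gene_id(raw$gene_id)
  if (any(ids == ""))
    stop(sprintf("annotation parse error at line %d: empty gene_id",
                 which(ids == "")[1] + 1L))
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation: ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  flags <- vapply(seq_along(ids), function(i) parse_flag(raw$is_membrane[i], i),
                  logical(1))
  drugs <- lapply(raw$drugs, function(d) {
    parts <- trimws(strsplit(d, ";", fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  })
  out <- data.frame(gene_id = ids, is_membrane = flags,
                    stringsAsFactors = FALSE)
  out$drugs <- drugs
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Attach membrane/drug annotations to a key-gene table
#'
#' Left-joins the annotation on the (uppercased, trimmed) gene id; genes
#' absent from the annotation are marked unknown (\code{is_membrane = NA},
#' no drugs). Idempotent: re-annotating with the same table changes
#' nothing. Counts of membrane-flagged and drug-associated genes are
#' attached as attributes \code{n_membrane} and \code{n_drug};
#' unmatched gene ids as attribute \code{unmatched}.
#'
#' @param key A \code{key_gene_table} from \code{\link{select_key_genes}}
#'   (any data.frame with a \code{gene_id} column works).
#' @param ann An \code{\link{read_annotation_table}} result (or a
#'   data.frame with \code{gene_id}, \code{is_membrane}, \code{drugs}).
#' @return The key table with \code{is_membrane} and \code{drugs} columns.
#' @export
annotate_key_genes <- function(key, ann) {
  ids <- norm_gene_id(key$gene_id)
  m <- match(ids, norm_gene_id(ann$gene_id))
  key$is_membrane <- ann$is_membrane[m]
  drugs <- vector("list", length(ids))
  hit <- !is.na(m)
  drugs[hit] <- ann$drugs[m[hit]]
  drugs[!hit] <- list(character(0))
  key$drugs <- drugs
  attr(key, "n_membrane") <- sum(key$is_membrane, na.rm = TRUE)
  attr(key, "n_drug") <- sum(lengths(key$drugs) > 0)
  attr(key, "unmatched") <- key$gene_id[!hit]
  key
}

#' Read a gene-gene interaction edge list
#'
#' TSV with columns \code{gene_a}, \code{gene_b} and optionally
#' \code{type}. Self-loops are dropped and duplicate undirected edges
#' (regardless of endpoint order) are collapsed. Gene ids are uppercased
#' and trimmed.
#'
#' @param path Path to the edge TSV.
#' @return An \code{edge_list}: data.frame with \code{gene_a},
#'   \code{gene_b}, \code{type}.
#' @export
read_edge_list <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(raw)))
    stop("edge file needs columns gene_a, gene_b")
  edge_list(raw$gene_a, raw$gene_b,
            if ("type" %in% names(raw)) raw$type else NA_character_)
}

#' Construct an edge list from vectors
#'
#' @param gene_a,gene_b Endpoint gene ids.
#' @param type Optional edge type label.
#' @return An \code{edge_list} data.frame (self-loops removed, undirected
#'   duplicates collapsed, keeping the first occurrence's type).
#' @export
edge_list <- function(gene_a, gene_b, type = NA_character_) {
  a <- norm_gene_id(gene_a); b <- norm_gene_id(gene_b)
  type <- rep_len(as.character(type), length(a))
  keep <- a != b
  a <- a[keep]; b <- b[keep]; type <- type[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dupe <- duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(gene_a = lo[!dupe], gene_b = hi[!dupe],
                    type = type[!dupe], stringsAsFactors = FALSE)
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Rank hub genes on an interaction network
#'
#' Computes each key gene's degree over the collapsed undirected edge set
#' and returns the genes with degree strictly above \code{degree_min} and
#' |Log2FC| strictly above \code{abs_lfc_min}, ordered by degree
#' descending, then |Log2FC| descending, then lexicographically.
#'
#' @param edges An \code{\link{edge_list}} (endpoints need not all be key
#'   genes).
#' @param key A \code{key_gene_table} with \code{gene_id} and
#'   \code{log2fc} columns.
#' @param degree_min Minimum degree (strict >).
#' @param abs_lfc_min Minimum |Log2FC| (strict >).
#' @param edge_types Optional filter: keep only edges of these types.
#' @return data.frame with \code{gene_id}, \code{degree}, \code{log2fc}.
#' @export
hub_rank <- function(edges, key, degree_min, abs_lfc_min, edge_types = NULL) {
  if (!is.null(edge_types))
    edges <- edges[edges$type %in% edge_types, , drop = FALSE]
  ids <- norm_gene_id(key$gene_id)
  endpoints <- c(edges$gene_a, edges$gene_b)
  deg <- table(endpoints)
  degree <- ifelse(ids %in% names(deg), as.integer(deg[ids]), 0L)
  out <- data.frame(gene_id = key$gene_id, degree = degree,
                    log2fc = key$log2fc, stringsAsFactors = FALSE)
  out <- out[out$degree > degree_min & abs(out$log2fc) > abs_lfc_min, ,
             drop = FALSE]
  out <- out[order(-out$degree, -abs(out$log2fc), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the pipeline's publication-style outputs
#'
#' Writes \code{fold_results.tsv} (per repeat/fold/method/N metrics),
#' \code{stability.tsv} (per-method summary incl. ASM),
#' \code{key_genes.tsv} (consensus table; drug lists joined by ";"),
#' \code{config.yaml} (configuration echo) and \code{run_summary.txt}.
#'
#' @param result An \code{ensemble_result}.
#' @param key A \code{key_gene_table} (optional).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the files written.
#' @export
write_ensemble_outputs <- function(result, key = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(fold = file.path(dir, "fold_results.tsv"),
             stability = file.path(dir, "stability.tsv"),
             config = file.path(dir, "config.yaml"),
             summary = file.path(dir, "run_summary.txt"))
  write.table(result$fold_metrics, files["fold"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$summary, files["stability"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(result$config, files["config"])
  if (!is.null(key)) {
    files["key"] <- file.path(dir, "key_genes.tsv")
    flat <- key
    if (!is.null(flat$drugs))
      flat$drugs <- vapply(flat$drugs, paste, character(1), collapse = ";")
    write.table(as.data.frame(flat), files["key"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  lines <- c(
    sprintf("ensemble run: %d repeats x %d folds, %d genes, %d samples",
            result$config$n_repeats, result$config$n_folds,
            nrow(result$dataset$values), ncol(result$dataset$values)),
    sprintf("methods: %s", paste(result$config$methods, collapse = ", ")),
    sprintf("status: %s (%d failed cells)", result$status,
            length(result$errors)),
    if (!is.null(key))
      sprintf("key genes: %d (union of %s per-method top-%d sets)",
              nrow(key), length(attr(key, "methods")), attr(key, "n")))
  writeLines(lines, files["summary"])
  invisible(files)
}
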