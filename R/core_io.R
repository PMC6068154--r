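#' Construct a gene alignment object
#'
#' An alignment is one gene's gapped multiple sequence alignment within a
#' species-level viral group. Residues are stored as an uppercase character
#' matrix (sequences in rows) so downstream column operations are cheap.
#'
#' @param gene_id Gene identifier (typically the FASTA filename stem).
#' @param group_id Viral group identifier (typically the directory name).
#' @param mat Character matrix, one row per sequence, one column per aligned
#'   position. Row names are the sequence ids. Lowercase residues are
#'   normalized to uppercase.
#' @return An object of class `phg_alignment` with elements `gene_id`,
#'   `group_id`, `mat`, `n_seqs` and `raw_length`.
#' @export
alignment <- function(gene_id, group_id, mat) {
  if (!is.matrix(mat) || !is.character(mat)) {
    stop("`mat` must be a character matrix")
  }
  if (nrow(mat) < 1L) stop("alignment must contain at least one sequence")
  ids <- rownames(mat)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must be named (matrix row names)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in gene '", gene_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat[] <- toupper(mat)
  structure(
    list(gene_id = as.character(gene_id), group_id = as.character(group_id),
         mat = mat, n_seqs = nrow(mat), raw_length = ncol(mat)),
    class = "phg_alignment"
  )
}

#' @export
print.phg_alignment <- function(x, ...) {
  cat(sprintf("<phg_alignment> gene %s (group %s): %d sequences x %d columns\n",
              x$gene_id, x$group_id, x$n_seqs, x$raw_length))
  invisible(x)
}

#' Read one gapped FASTA alignment
#'
#' @param path Path to a multi-record FASTA file.
#' @param gene_id,group_id Identifiers to attach; default to the filename
#'   stem and the parent directory name.
#' @return A [alignment()] object.
#' @export
read_alignment <- function(path,
                           gene_id = tools::file_path_sans_ext(basename(path)),
                           group_id = basename(dirname(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("cannot parse FASTA '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    stop("unequal sequence lengths in '", path, "' (",
         paste(range(w), collapse = "-"), "): not an alignment")
  }
  # FASTA headers may carry descriptions; the id is the first token
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  m <- as.matrix(seqs)
  rownames(m) <- ids
  alignment(gene_id, group_id, m)
}

#' Read a cohort of per-gene alignments organized by viral group
#'
#' Expects one subdirectory per viral group under `root_path`, each holding
#' per-gene aligned FASTA files (`.fa`, `.fas`, `.fasta`, `.fna`, `.aln`,
#' case-insensitive). The gene id is the filename stem and the group id the
#' directory name. Files that fail to parse (unequal lengths, duplicate ids,
#' empty) are skipped with a warning naming the file, so one corrupt export
#' does not abort a cohort run.
#'
#' @param root_path Cohort root directory.
#' @return Named list (one element per group, lexicographic order) of lists
#'   of [alignment()] objects (lexicographic by gene id).
#' @export
read_cohort <- function(root_path) {
  if (!dir.exists(root_path)) stop("no such directory: ", root_path)
  groups <- list.dirs(root_path, full.names = FALSE, recursive = FALSE)
  groups <- sort_c(groups)
  if (length(groups) == 0L) {
    warning("no group subdirectories under ", root_path)
    return(list())
  }
  out <- vector("list", length(groups))
  names(out) <- groups
  for (g in groups) {
    files <- list.files(file.path(root_path, g),
                        pattern = "\\.(fa|fas|fasta|fna|aln)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order_c(tools::file_path_sans_ext(basename(files)))]
    alns <- list()
    for (f in files) {
      a <- tryCatch(read_alignment(f, group_id = g),
                    error = function(e) {
                      warning("skipping '", f, "': ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
      if (!is.null(a)) alns[[a$gene_id]] <- a
    }
    out[[g]] <- alns
  }
  out
}

#' Read the viral-group metadata table
#'
#' Tab-separated with header columns `group_id`, `sample_type`,
#' `host_species` and optionally `is_oral`. When `is_oral` is absent it is
#' derived from the sample type: `TRUE` iff the label starts with "oral"
#' (case-insensitive), mirroring the oral-versus-other dichotomy used for
#' sample-origin enrichment while keeping the detailed labels.
#'
#' @param path Path to the table.
#' @return data.frame with columns group_id, sample_type, is_oral,
#'   host_species.
#' @export
read_group_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("group_id", "sample_type", "host_species")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("metadata table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$group_id)) {
    stop("duplicate group_id in metadata: ",
         paste(unique(df$group_id[duplicated(df$group_id)]), collapse = ", "))
  }
  if ("is_oral" %in% names(df)) {
    is_oral <- toupper(trimws(df$is_oral)) %in% c("TRUE", "T", "1", "YES")
  } else {
    is_oral <- grepl("^oral", trimws(df$sample_type), ignore.case = TRUE)
  }
  data.frame(group_id = df$group_id, sample_type = df$sample_type,
             is_oral = is_oral, host_species = df$host_species,
             stringsAsFactors = FALSE)
}

#' Read the host-immunity frequency table
#'
#' Tab-separated with header `species`, `n_genomes`, `freq_type1`,
#' `freq_type2`, `freq_type3`, `freq_crispr`. Frequencies are the fraction
#' of sequenced individuals of a host bacterial species carrying Type I/II/III
#' restriction endonucleases or a CRISPR array, and must lie in [0, 1].
#'
#' @param path Path to the table.
#' @return data.frame of host immunity profiles.
#' @export
read_immunity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("species", "n_genomes", "freq_type1", "freq_type2",
            "freq_type3", "freq_crispr")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("immunity table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("immunity table is empty: ", path)
    return(df[, need])
  }
  fcols <- c("freq_type1", "freq_type2", "freq_type3", "freq_crispr")
  for (col in fcols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop("non-numeric ", col, " in immunity table row(s) ",
           paste(bad, collapse = ", "))
    }
    out <- which(v < 0 | v > 1)
    if (length(out) > 0L) {
      stop(col, " outside [0,1] in immunity table row(s) ",
           paste(out, collapse = ", "))
    }
    df[[col]] <- v
  }
  df$n_genomes <- as.integer(df$n_genomes)
  df[, need]
}

#' Write a result table as tab-separated text
#'
#' Floating-point columns are rendered with 8 significant digits so that a
#' write/read round trip preserves values to well beyond measurement
#' precision; column order is preserved as given.
#'
#' @param records data.frame to write.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- vapply(v, function(x) {
        if (is.na(x)) "" else format(x, digits = 8, scientific = FALSE,
                                     trim = TRUE)
      }, character(1))
      out[[j]] <- s
    } else if (is.logical(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "", ifelse(out[[j]], "TRUE", "FALSE"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# minimal-overhead data.frame for hot loops (no name repair, no coercion)
quick_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1L]])))
}

# fast internal constructor: caller guarantees uppercase residues, unique
# non-empty row names (used by the simulator, which builds matrices itself)
new_alignment <- function(gene_id, group_id, mat) {
  structure(
    list(gene_id = gene_id, group_id = group_id, mat = mat,
         n_seqs = nrow(mat), raw_length = ncol(mat)),
    class = "phg_alignment"
  )
}

# Locale-independent character sorting, so output ordering is identical
# across machines.
sort_c <- function(x) x[order_c(x)]
order_c <- function(x) order(x, method = "radix")
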