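#' Read a gene-expression matrix from CSV/TSV
#'
#' Expects a header row of sample labels and one row per gene with the gene
#' identifier in the first column. The field separator (comma or tab) is
#' sniffed from the header line. Duplicate gene identifiers, non-numeric
#' cells, and rows containing missing values are rejected with errors naming
#' the offenders.
#'
#' @param path file path.
#' @return List with `gene_names`, `expression` (p x m numeric matrix with
#'   gene row names), and `sample_labels`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (ncol(df) < 3L) stop("expected a gene-id column plus >= 2 sample columns")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  bad_col <- names(body)[!vapply(body, is.numeric, TRUE)]
  if (length(bad_col))
    stop("non-numeric expression values in columns: ",
         paste(bad_col, collapse = ", "))
  mat <- as.matrix(body)
  bad_row <- ids[rowSums(!is.finite(mat)) > 0]
  if (length(bad_row))
    stop("missing or non-finite values in genes: ",
         paste(bad_row, collapse = ", "))
  rownames(mat) <- ids
  list(gene_names = ids, expression = mat, sample_labels = colnames(mat))
}

#' Write a time-varying network to adjacency CSVs and SIF edge lists
#'
#' One pair of files per epoch and method: a genes x genes signed-weight
#' adjacency CSV (gene names as header and first column, 12 significant
#' digits) and a SIF edge list with lines `source <sign> target` where
#' `<sign>` is `+` or `-` after the sign of the weight. Edges are emitted in
#' row-major gene order, so outputs are deterministic.
#'
#' @param net an `"akron_networks"` object from [track_epochs()] /
#'   [track_network()].
#' @param outdir output directory (created if needed).
#' @param methods which network variants to write; defaults to all present.
#' @param tol entries with `|w| <= tol` are omitted from the SIF files.
#' @return Invisibly, the character vector of files written.
#' @export
write_network <- function(net, outdir, methods = NULL, tol = 0) {
  stopifnot(inherits(net, "akron_networks"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  present <- intersect(c("kf", "l1", "akron", "kf_s", "l1_s", "akron_s"),
                       names(net))
  if (is.null(methods)) methods <- present
  if (!all(methods %in% present))
    stop("unknown methods: ", paste(setdiff(methods, present), collapse = ", "))
  genes <- net$gene_names
  written <- character(0)
  for (m in methods) {
    for (k in seq_along(net[[m]])) {
      A <- net[[m]][[k]]
      csv <- file.path(outdir, sprintf("%s_epoch%02d.csv", m, k))
      dfr <- data.frame(gene = genes,
                        apply(A, 2, function(v) signif(v, 12)),
                        check.names = FALSE)
      colnames(dfr) <- c("gene", genes)
      utils::write.table(dfr, csv, sep = ",", row.names = FALSE,
                         quote = FALSE)
      sif <- file.path(outdir, sprintf("%s_epoch%02d.sif", m, k))
      lines <- character(0)
      for (i in seq_along(genes)) {
        nz <- which(abs(A[i, ]) > tol)
        if (length(nz))
          lines <- c(lines, sprintf("%s\t%s\t%s", genes[i],
                                    ifelse(A[i, nz] > 0, "+", "-"),
                                    genes[nz]))
      }
      writeLines(lines, sif)
      written <- c(written, csv, sif)
    }
  }
  invisible(written)
}

#' Read one per-epoch adjacency CSV written by [write_network()]
#'
#' @param path CSV file path.
#' @return Numeric matrix with gene dimnames.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  mat
}

#' Read an under-determined system from plain CSV files
#'
#' @param phi_path header-free numeric CSV holding the n x p matrix.
#' @param y_path file holding the n observation values (one per line or
#'   comma-separated).
#' @param noise_eps noise threshold passed through to
#'   [underdetermined_system()].
#' @return An `"akron_system"`.
#' @export
read_system <- function(phi_path, y_path, noise_eps = 0) {
  phi <- as.matrix(utils::read.table(phi_path, header = FALSE, sep = ","))
  y <- scan(y_path, sep = ",", quiet = TRUE)
  y <- y[!is.na(y)]
  underdetermined_system(unname(phi), y, noise_eps = noise_eps)
}

#' Run the packaged worked example of the neighborhood search
#'
#' Solves the embedded 3x5 system ([example_system()]) by basis pursuit,
#' then runs the AKRON search with the given neighborhood size seeded by the
#' l1 solution, printing the seed, every candidate zero set with its
#' residual and zero count, and the returned solution. With `delta = 1` the
#' search evaluates exactly 3 candidate supports and restores the two zero
#' locations the l1 solution misplaces.
#'
#' The check at the end compares the returned solution against the known
#' sparsest solution of the system, `(0, 0, 0, -1.2372, 1.04858)`, using a
#' tolerance of `2e-2`: the system's coefficients are stored to four
#' decimals, and that input precision propagates to about a percent in the
#' re-solved coordinates.
#'
#' @param delta neighborhood size (default 1).
#' @param quiet suppress printing.
#' @return Invisibly, a list with `l1` and `akron` solutions, `candidates`
#'   (data.frame), and logical `ok`.
#' @export
run_worked_example <- function(delta = 1L, quiet = FALSE) {
  sys <- example_system()
  seed <- basis_pursuit(sys)
  pool <- seed_pool(seed$x, sys$s + delta)
  cand_sets <- subsets_of(pool, sys$s)
  cands <- lapply(cand_sets, function(zs) solve_zero_set(sys, sort(zs)))
  sol <- akron(sys, seed, delta = delta)
  target <- c(0, 0, 0, -1.2372, 1.04858)
  ok <- identical(sort(which(abs(sol$x) <= 1e-3 * max(abs(sol$x)))), 1:3) &&
    max(abs(sol$x - target)) <= 2e-2
  cand_df <- data.frame(
    zero_set = vapply(cands, function(s)
      paste0("{", paste(s$zero_set, collapse = ","), "}"), ""),
    residual = vapply(cands, `[[`, numeric(1), "residual"),
    num_zeros = vapply(cands, `[[`, numeric(1), "num_zeros"),
    l1 = vapply(cands, `[[`, numeric(1), "l1"))
  if (!quiet) {
    cat("Worked example: 3 equations, 5 unknowns, kernel dimension s = 2\n\n")
    cat("l1 seed (basis pursuit):\n  ",
        paste(sprintf("% .4f", seed$x), collapse = "  "), "\n\n")
    cat(sprintf("delta = %d neighborhood: pool = {%s}, %d candidate zero set(s)\n",
                delta, paste(sort(pool), collapse = ","), length(cands)))
    print(cand_df, row.names = FALSE, digits = 4)
    cat("\nreturned solution:\n  ",
        paste(sprintf("% .5f", sol$x), collapse = "  "), "\n")
    cat(sprintf("residual %.2e, %d zeros counted; %s\n", sol$residual,
                sol$num_zeros,
                if (ok) "matches the known sparsest solution"
                else "DOES NOT match the known sparsest solution"))
  }
  invisible(list(l1 = seed, akron = sol, candidates = cand_df, ok = ok))
}
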