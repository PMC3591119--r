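# Step-1 TM-align emulation: iterative refinement from every seed, best
# final affine-gap score wins.
tmalign_align <- function(a, b, seeds, max_iter = 100L) {
  best <- NULL
  for (s in seeds) {
    al <- tmscore_align(a, b, s, refine = TRUE, max_iter = max_iter)
    if (alignment_length(al) == 0L) next
    if (is.null(best) || al$score > best$score) best <- al
  }
  if (is.null(best))
    return(list(alignment = alignment(integer(0), integer(0), 0, "tmalign"),
                transform = transform_identity(), score = NA_real_,
                no_alignment = TRUE))
  list(alignment = best, transform = attr(best, "transform"),
       score = best$score, no_alignment = FALSE)
}

# Alignment step of one method on a fixed (deep-search) superposition.
align_on_transform <- function(method, a, b, tr, d) {
  b_hat <- apply_transform(tr, b)
  switch(method,
    structal = dp_linear(structal_score_matrix(a, b_hat), gap = 10,
                         scheme = "structal"),
    tmalign = tmscore_align(a, b, tr),
    lock2 = lock2_final_alignment(a, b_hat, d = d),
    stop("unknown method: ", method))
}

#' Run the two-step protocol on one structure pair
#'
#' Step 1 runs each selected heuristic aligner from its own fragment
#' seeds; step 2 runs the deep superposition search ([maxpairs_search()])
#' and recomputes each method's alignment step on the deep-search
#' superposition. Quality metrics are reported for both passes, together
#' with their per-metric deltas (deep-search minus original). Per-method
#' failures are isolated: the run continues and the failure is recorded.
#'
#' @param a,b structures, or PDB file paths (then `chain_a`/`chain_b`
#'   select the chains).
#' @param methods subset of `c("structal", "tmalign", "lock2")`.
#' @param d distance cutoff for NumPairs/PSI and the search (Angstroms).
#' @param params [search_params()] for the deep search.
#' @param ref optional reference [alignment] for shift agreement.
#' @param pair_id label used in the output table.
#' @param chain_a,chain_b chains to read when `a`/`b` are file paths.
#' @param s_max largest shift tolerance for agreement curves.
#' @return A list of class `benchmark_row`: `table` (one row per method
#'   and pass with the [quality_report()] metrics and, when `ref` is
#'   given, the zero-shift agreement), `deltas`, `agreement` (curves per
#'   method/pass), `search` (the [maxpairs_search()] result), `errors`.
#' @export
run_pair <- function(a, b, methods = c("structal", "tmalign", "lock2"),
                     d = 3, params = search_params(d = d), ref = NULL,
                     pair_id = NULL, chain_a = NULL, chain_b = NULL,
                     s_max = 5L) {
  if (is.character(a)) a <- read_pdb_ca(a, chain_a)
  if (is.character(b)) b <- read_pdb_ca(b, chain_b)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(pair_id)) pair_id <- paste(a$id, b$id, sep = "-")
  seeds <- default_seeds(a, b)
  search <- maxpairs_search(a, b, params)
  rows <- list()
  curves <- list()
  errors <- list()
  for (m in methods) {
    res <- tryCatch({
      step1 <- switch(m,
        structal = structal_align(a, b, seeds),
        tmalign = tmalign_align(a, b, seeds),
        lock2 = lock2_align(a, b, seeds, d = d))
      al2 <- align_on_transform(m, a, b, search$transform, d)
      list(list(al = step1$alignment, tr = step1$transform,
                pass = "original"),
           list(al = al2, tr = search$transform, pass = "deepsearch"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[m]] <- conditionMessage(res)
      next
    }
    for (r in res) {
      qr <- quality_report(r$al, a, b, r$tr, d = d)
      qr <- cbind(data.frame(pair_id = pair_id, method = m, pass = r$pass),
                  qr)
      qr$agreement_s0 <- NA_real_
      if (!is.null(ref) && alignment_length(ref) > 0L) {
        curve <- shift_agreement(r$al, ref, s_max = s_max)
        curves[[paste(m, r$pass, sep = ".")]] <- curve
        qr$agreement_s0 <- curve$agreement[curve$s == 0]
      }
      rows[[length(rows) + 1L]] <- qr
    }
  }
  table <- do.call(rbind, rows)
  structure(list(table = table, deltas = pair_deltas(table),
                 agreement = curves, search = search, errors = errors),
            class = "benchmark_row")
}

# Deep-search minus original, per method and metric.
pair_deltas <- function(table) {
  if (is.null(table) || !nrow(table)) return(NULL)
  metrics <- c("nmat", "numpairs_d", "psi_d", "si", "crms_aligned",
               "agreement_s0")
  out <- list()
  for (m in unique(table$method)) {
    o <- table[table$method == m & table$pass == "original", , drop = FALSE]
    n <- table[table$method == m & table$pass == "deepsearch", , drop = FALSE]
    if (nrow(o) != 1L || nrow(n) != 1L) next
    out[[length(out) + 1L]] <- cbind(
      data.frame(pair_id = o$pair_id, method = m),
      as.data.frame(as.list(setNames(
        unlist(n[metrics]) - unlist(o[metrics]), metrics))))
  }
  do.call(rbind, out)
}

#' @export
print.benchmark_row <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Run the two-step protocol over a benchmark manifest
#'
#' Applies [run_pair()] to every pair of a manifest (see
#' [read_manifest()]); unreadable or failing pairs are skipped with a
#' warning and the aggregates cover completed pairs only. Aggregates are
#' arithmetic means over pairs (per method, pass and metric), computed
#' overall and per manifest tag when tags are present; missing per-method
#' values are excluded pairwise and the contributing pair counts
#' reported.
#'
#' @param manifest manifest file path or the data frame from
#'   [read_manifest()].
#' @param dir directory structure/reference paths in the manifest are
#'   relative to.
#' @inheritParams run_pair
#' @return A list of class `benchmark_result`: `rows` (stacked per-pair
#'   tables), `deltas`, `aggregates`, `failed` (named reasons).
#' @export
run_benchmark <- function(manifest, dir = ".",
                          methods = c("structal", "tmalign", "lock2"),
                          d = 3, params = search_params(d = d), s_max = 5L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- list(); deltas <- list(); failed <- list()
  for (r in seq_len(nrow(manifest))) {
    mr <- manifest[r, ]
    pid <- paste0(mr$pdb_a, mr$chain_a, "-", mr$pdb_b, mr$chain_b)
    res <- tryCatch({
      ref <- if (!is.na(mr$ref))
        read_reference_alignment(file.path(dir, mr$ref)) else NULL
      run_pair(file.path(dir, mr$pdb_a), file.path(dir, mr$pdb_b),
               methods = methods, d = d, params = params, ref = ref,
               pair_id = pid, chain_a = mr$chain_a, chain_b = mr$chain_b,
               s_max = s_max)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("pair ", pid, " skipped: ", conditionMessage(res),
              call. = FALSE)
      failed[[pid]] <- conditionMessage(res)
      next
    }
    tab <- res$table
    tab$tag <- mr$tag
    rows[[length(rows) + 1L]] <- tab
    if (!is.null(res$deltas)) deltas[[length(deltas) + 1L]] <- res$deltas
  }
  rows <- do.call(rbind, rows)
  deltas <- do.call(rbind, deltas)
  structure(list(rows = rows, deltas = deltas,
                 aggregates = benchmark_aggregates(rows), failed = failed),
            class = "benchmark_result")
}

# Per-(method, pass) means of the quality metrics, overall and per tag.
benchmark_aggregates <- function(rows) {
  if (is.null(rows) || !nrow(rows)) return(NULL)
  metrics <- c("nmat", "crms_aligned", "numpairs_d", "psi_d", "si",
               "agreement_s0")
  one <- function(sub, tag) {
    do.call(rbind, lapply(split(sub, list(sub$method, sub$pass)),
      function(g) {
        if (!nrow(g)) return(NULL)
        means <- vapply(metrics, function(mc) mean(g[[mc]], na.rm = TRUE),
                        numeric(1))
        cbind(data.frame(subset = tag, method = g$method[1],
                         pass = g$pass[1], n_pairs = nrow(g)),
              as.data.frame(as.list(means)))
      }))
  }
  out <- one(rows, "all")
  tags <- unique(rows$tag[!is.na(rows$tag)])
  for (tg in tags) out <- rbind(out, one(rows[!is.na(rows$tag) &
                                                rows$tag == tg, ], tg))
  rownames(out) <- NULL
  out
}

#' Write and read result tables as TSV
#'
#' Plain tab-separated serialization for benchmark tables and agreement
#' curves; `read_tsv_report(write_tsv_report(x, path))` reproduces the
#' data frame.
#'
#' @param x a data frame.
#' @param path file path.
#' @return `write_tsv_report()` returns `path` invisibly;
#'   `read_tsv_report()` the data frame.
#' @export
write_tsv_report <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @param auto_unbox passed to [jsonlite::toJSON()] semantics for scalar
#'   fields.
#' @rdname write_tsv_report
#' @export
write_json_report <- function(x, path, auto_unbox = TRUE) {
  jsonlite::write_json(x, path, auto_unbox = auto_unbox, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
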