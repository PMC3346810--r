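#' Read and write interaction matrices
#'
#' TSV format: `n` rows of `n` tab-separated integers in `{-1, 0, 1}`;
#' lines starting with `#` are comments. JSON format:
#' `{"n": <int>, "entries": [[...], ...]}`. Writing then reading either
#' format round-trips exactly.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return `read_tbn` returns a validated interaction matrix; `write_tbn`
#'   returns `path` invisibly.
#' @export
read_tbn <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (!file.exists(path)) stop_invalid(paste0("file not found: ", path))
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.null(obj$entries)) stop_invalid("JSON matrix must have 'entries'")
    entries <- as.matrix(obj$entries)
    if (!is.null(obj$n) && (nrow(entries) != obj$n || ncol(entries) != obj$n))
      stop_invalid(sprintf("JSON declares n = %d but entries are %d x %d",
                           obj$n, nrow(entries), ncol(entries)))
    return(tbn_network(entries))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop_invalid("no matrix rows in file")
  rows <- lapply(seq_along(lines), function(r) {
    parts <- strsplit(trimws(lines[r]), "[\t ]+")[[1]]
    vals <- suppressWarnings(as.integer(parts))
    if (anyNA(vals))
      stop_invalid(sprintf("row %d, column %d: '%s' is not an integer",
                           r, which(is.na(vals))[1],
                           parts[which(is.na(vals))[1]]))
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1 || ncols[1] != length(rows))
    stop_invalid(sprintf(
      "matrix must be square: %d rows but row widths %s",
      length(rows), paste(unique(ncols), collapse = ", ")))
  tbn_network(do.call(rbind, rows))
}

#' @param A interaction matrix to write.
#' @rdname read_tbn
#' @export
write_tbn <- function(A, path, format = c("auto", "tsv", "json")) {
  A <- check_tbn(A)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(list(n = nrow(A), entries = A), path,
                         auto_unbox = TRUE)
  } else {
    writeLines(apply(A, 1, paste, collapse = "\t"), path)
  }
  invisible(path)
}

#' Full analysis report for one network
#'
#' Composes attractor enumeration, Ergodic Set extraction, stationary
#' distributions (both plain and penalized) and — when the network has a
#' single ES — the deletion sensitivity with its displacement
#' decomposition, into one report suitable for JSON serialization. For a
#' multi-ES network the ESs are still reported and `S` is `NA` (undefined).
#'
#' @param A interaction matrix.
#' @param lambda penalty weight.
#' @return a `tbn_report` list: `n`, `matrix`, `lambda`, `attractors`
#'   (keys, lengths, kinds), `n_es`, `ergodic_sets` (member keys with plain
#'   `pi` and penalized `pi_tilde`), `sensitivity` (a
#'   [deletion_sensitivity()] report, or `NULL` when undefined).
#' @export
analyze_tbn <- function(A, lambda = 0.5) {
  A <- check_tbn(A)
  check_capacity(nrow(A))
  check_lambda(lambda)
  g <- attractor_graph(A)
  plain <- ergodic_sets(g, lambda = 1, use_penalty = FALSE)
  pen <- ergodic_sets(g, lambda = lambda, use_penalty = TRUE)
  ess <- lapply(seq_along(plain), function(k) {
    list(members = plain[[k]]$keys,
         pi = as.list(plain[[k]]$stationary),
         pi_tilde = as.list(pen[[k]]$stationary))
  })
  sens <- NULL
  if (length(plain) == 1 && any(A != 0L))
    sens <- deletion_sensitivity(A, lambda = lambda, use_penalty = TRUE)
  structure(
    list(n = nrow(A), matrix = A, lambda = lambda,
         attractors = data.frame(
           key = vapply(g$attractors, `[[`, character(1), "key"),
           length = vapply(g$attractors, `[[`, integer(1), "length"),
           kind = vapply(g$attractors, `[[`, character(1), "kind")),
         n_es = length(plain),
         ergodic_sets = ess,
         sensitivity = sens),
    class = "tbn_report")
}

#' @export
print.tbn_report <- function(x, ...) {
  cat(sprintf("<network report: %d genes, %d attractors, %d Ergodic Set(s)>\n",
              x$n, nrow(x$attractors), x$n_es))
  if (is.null(x$sensitivity)) {
    cat("  sensitivity: undefined (multiple Ergodic Sets or no edges)\n")
  } else {
    cat(sprintf("  S = %.4f (lambda = %g), S x D = %.4f\n",
                x$sensitivity$S, x$lambda, x$sensitivity$discounted_fitness))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report a `tbn_report` from [analyze_tbn()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    tool = "tbnsens",
    version = as.character(utils::packageVersion("tbnsens")),
    n = report$n,
    matrix = report$matrix,
    lambda = report$lambda,
    attractors = report$attractors,
    n_es = report$n_es,
    ergodic_sets = report$ergodic_sets)
  if (!is.null(report$sensitivity)) {
    s <- report$sensitivity
    obj$sensitivity <- list(
      S = s$S, discounted_fitness = s$discounted_fitness,
      lambda = s$lambda, use_penalty = s$use_penalty,
      wt_es_size = s$wt_es_size, wt_mean_length = s$wt_mean_length,
      per_mutant = s$per_mutant, skipped = s$skipped)
  } else {
    obj$sensitivity <- "undefined"
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' GraphViz DOT export of a flip-transition graph
#'
#' Renders the attractor transition structure (transition multiplicities as
#' edge labels, Ergodic Set members filled) for figures of the kind used to
#' illustrate Ergodic Sets.
#'
#' @param graph a `tbn_graph`.
#' @param path optional file to write; when `NULL` the DOT text is
#'   returned.
#' @param include_self include self-transitions (often omitted in figures).
#' @return DOT source as a character scalar (invisibly when written).
#' @export
graph_dot <- function(graph, path = NULL, include_self = FALSE) {
  ess <- ergodic_sets(graph, lambda = 1, use_penalty = FALSE)
  in_es <- unique(unlist(lapply(ess, `[[`, "attractor_indices")))
  tr <- graph$transitions
  agg <- stats::aggregate(state ~ from + to, data = tr, FUN = length)
  lines <- c("digraph ergodic_sets {", "  rankdir=LR;")
  for (a in seq_along(graph$attractors)) {
    att <- graph$attractors[[a]]
    lines <- c(lines, sprintf(
      "  a%d [label=\"%s\\n(L=%d)\"%s];", a, att$key, att$length,
      if (a %in% in_es) ", style=filled, fillcolor=gold" else ""))
  }
  for (k in seq_len(nrow(agg))) {
    if (!include_self && agg$from[k] == agg$to[k]) next
    lines <- c(lines, sprintf("  a%d -> a%d [label=\"%d\"];",
                              agg$from[k], agg$to[k], agg$state[k]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
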