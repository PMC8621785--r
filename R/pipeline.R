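#' Detection configuration
#'
#' All tunable thresholds of the detection pipeline, logged verbatim into
#' every result record for reproducibility.
#'
#' @param max_ss_dist geometric disulfide SG-SG threshold, Angstrom.
#' @param use_links honour LINK/SSBOND/struct_conn records.
#' @param permissive distance-based non-disulfide bridge detection.
#' @param min_loop_span minimal loop span in residues.
#' @param max_loop_gap largest tolerated in-loop gap (validity test).
#' @param min_tail_depth,cancel_eps,cancel_sep see [reduce_params()].
#' @param flip_signs globally mirror the piercing sign convention (the
#'   right-hand-rule convention used here is internally consistent but may
#'   be mirrored relative to other software; all sign statistics are
#'   convention-relative).
#' @param window stability profile smoothing window.
#' @param max_iter,rel_tol,max_edge see [min_params()].
#' @param stability compute a per-piercing stability report.
#' @return list of class `lasso_config`.
#' @export
lasso_config <- function(max_ss_dist = 2.5, use_links = TRUE, permissive = FALSE,
                         min_loop_span = 4L, max_loop_gap = 2L,
                         min_tail_depth = 3L, cancel_eps = 2.0, cancel_sep = 1L,
                         flip_signs = FALSE, window = 5L,
                         max_iter = 200L, rel_tol = 1e-4, max_edge = NULL,
                         stability = FALSE) {
  structure(list(max_ss_dist = max_ss_dist, use_links = use_links,
                 permissive = permissive, min_loop_span = as.integer(min_loop_span),
                 max_loop_gap = as.integer(max_loop_gap),
                 min_tail_depth = as.integer(min_tail_depth),
                 cancel_eps = cancel_eps, cancel_sep = as.integer(cancel_sep),
                 flip_signs = flip_signs, window = as.integer(window),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 max_edge = max_edge, stability = stability),
            class = "lasso_config")
}

#' Detect and classify all lasso motifs of one chain
#'
#' Full pipeline: gap modelling, bridge detection, covalent-loop extraction,
#' per-loop surface spanning and minimization, oriented crossing detection
#' for both tails, reduction to genuine piercings, lasso-type
#' classification, fingerprint assembly, validity assessment, and (on
#' request) stability scoring. Per-loop failures (e.g. a degenerate
#' surface) are isolated: the loop is reported with an `error` field and
#' the other loops proceed. Deterministic for a given chain and config.
#'
#' @param chain a `lasso_chain`.
#' @param config a [lasso_config()].
#' @param bridges optional pre-computed bridge table ([detect_bridges()]
#'   output); detected from the chain when `NULL`.
#' @return object of class `lasso_result`.
#' @export
detect_chain <- function(chain, config = lasso_config(), bridges = NULL) {
  stopifnot(inherits(chain, "lasso_chain"))
  chain <- model_gaps(chain)
  if (is.null(bridges))
    bridges <- detect_bridges(chain, max_ss_dist = config$max_ss_dist,
                              use_links = config$use_links,
                              permissive = config$permissive)
  loops <- extract_loops(chain, bridges, min_span = config$min_loop_span)
  coords <- chain_coords(chain)
  n <- nrow(coords)
  rparams <- reduce_params(config$min_tail_depth, config$cancel_eps,
                           config$cancel_sep)
  mparams <- min_params(config$max_iter, config$rel_tol, config$max_edge)

  loop_records <- lapply(loops, function(lp) {
    rec <- list(res_i = lp$res_i, res_j = lp$res_j,
                chemistry = lp$bridge$chemistry, error = NULL)
    out <- tryCatch({
      surf <- minimize_surface(triangulate_loop(lp, chain), mparams)
      analyze <- function(idx, label) {
        cr <- if (length(idx) < 2L) empty_crossings()
              else find_crossings(surf, coords[idx, , drop = FALSE], label,
                                  tail_resid = idx)
        reduce_crossings(cr, tail_end_resid = if (length(idx)) idx[length(idx)] else 1L,
                         rparams)
      }
      n_idx <- if (lp$res_i > 1L) seq.int(lp$res_i, 1L) else integer()
      c_idx <- if (lp$res_j < n) seq.int(lp$res_j, n) else integer()
      pn <- analyze(n_idx, "N")
      pc <- analyze(c_idx, "C")
      # the loop threading its own surface is reported, not classified
      span_idx <- lp$span
      self_cr <- if (length(span_idx) > 3L)
        tryCatch(nrow(find_crossings(surf, coords[span_idx[-c(1L, length(span_idx))], ,
                                                  drop = FALSE], "C")),
                 error = function(e) NA_integer_)
      else 0L
      flip <- if (config$flip_signs) -1L else 1L
      type <- classify_loop(flip * pn$sign, flip * pc$sign)
      piercings <- rbind(pn, pc)
      if (nrow(piercings) > 0) piercings$sign <- flip * piercings$sign
      dist <- if (nrow(piercings) > 0)
        bridge_piercing_distance(lp, piercings) else NA_integer_
      val <- validate_loop(chain, lp, config$max_loop_gap, piercings)
      stab <- if (config$stability) stability_report(chain, piercings,
                                                    config$window) else NULL
      c(rec, list(type = type, minor = type$minor, major = type$major,
                  klass = type$klass, piercings = piercings,
                  bridge_distance = dist, validity = val,
                  surface_area = surf$area, converged = surf$converged,
                  self_crossings = self_cr, stability = stab))
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec$validity <- list(status = "artifact", reasons = "loop-analysis-failed")
      rec
    })
    out
  })

  ok <- !vapply(loop_records, function(r) is.null(r$type), logical(1L))
  fp <- lasso_fingerprint(lapply(loop_records[ok], `[[`, "type"))
  structure(list(chain_id = chain$id, n_residues = n,
                 bridges = bridges, loops = loop_records,
                 fingerprint = fp, config = config),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("Lasso detection for chain '%s' (%d residues)\n",
              x$chain_id, x$n_residues))
  cat(sprintf("  bridges: %d   covalent loops: %d   fingerprint: \"%s\"\n",
              nrow(x$bridges), length(x$loops), x$fingerprint$text))
  for (lp in x$loops) {
    if (!is.null(lp$error)) {
      cat(sprintf("  loop %d-%d (%s): ERROR %s\n", lp$res_i, lp$res_j,
                  lp$chemistry, lp$error))
    } else {
      cat(sprintf("  loop %d-%d (%s): %s [%s], %d piercing(s), status %s\n",
                  lp$res_i, lp$res_j, lp$chemistry, lp$minor, lp$klass,
                  nrow(lp$piercings), lp$validity$status))
    }
  }
  invisible(x)
}

#' @export
summary.lasso_result <- function(object, ...) {
  lt <- loop_table(object)
  cat(sprintf("Chain '%s': %d loop(s), fingerprint \"%s\"\n",
              object$chain_id, nrow(lt), object$fingerprint$text))
  if (nrow(lt)) print(lt, row.names = FALSE)
  invisible(lt)
}

#' Per-loop result table
#'
#' @param result a `lasso_result`.
#' @return data.frame with one row per covalent loop.
#' @export
loop_table <- function(result) {
  rows <- lapply(result$loops, function(lp) {
    data.frame(chain = result$chain_id, res_i = lp$res_i, res_j = lp$res_j,
               chemistry = lp$chemistry,
               minor = lp$minor %||NA% NA_character_,
               major = lp$major %||NA% NA_character_,
               n_piercings = if (is.null(lp$piercings)) NA_integer_
                             else nrow(lp$piercings),
               bridge_distance = lp$bridge_distance %||NA% NA_integer_,
               status = lp$validity$status)
  })
  if (length(rows) == 0L)
    return(data.frame(chain = character(), res_i = integer(), res_j = integer(),
                      chemistry = character(), minor = character(),
                      major = character(), n_piercings = integer(),
                      bridge_distance = integer(), status = character()))
  do.call(rbind, rows)
}

`%||NA%` <- function(a, b) if (is.null(a)) b else a

#' JSON record for a chain result
#'
#' @param result a `lasso_result`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @export
result_json <- function(result, path = NULL) {
  obj <- list(
    chain = result$chain_id,
    n_residues = result$n_residues,
    fingerprint = result$fingerprint$text,
    config = unclass(result$config),
    loops = lapply(result$loops, function(lp) {
      base <- list(res_i = lp$res_i, res_j = lp$res_j, chemistry = lp$chemistry)
      if (!is.null(lp$error)) return(c(base, list(error = lp$error)))
      c(base, list(minor = lp$minor, major = lp$major, klass = lp$klass,
                   n_signs = lp$type$n_signs, c_signs = lp$type$c_signs,
                   bridge_distance = lp$bridge_distance,
                   status = lp$validity$status,
                   reasons = lp$validity$reasons))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

#' Detect lassos in every chain of a structure file
#'
#' @param path structure file (PDB, mmCIF or xyz).
#' @param format see [read_structure()].
#' @param config a [lasso_config()].
#' @return list of `lasso_result`, one per chain.
#' @export
detect_file <- function(path, format = "auto", config = lasso_config()) {
  chains <- read_structure(path, format)
  lapply(chains, detect_chain, config = config)
}
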