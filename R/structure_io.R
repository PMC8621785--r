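#' Read a structure file into chains
#'
#' Reads PDB, mmCIF or plain xyz files and returns one [new_chain()] object
#' per polymer chain. ATOM/HETATM coordinate parsing for PDB and mmCIF goes
#' through \pkg{bio3d}; SSBOND/LINK (PDB) and `struct_conn` (mmCIF) records,
#' which bio3d does not expose, are scanned from the file directly and
#' attached to each chain for [detect_bridges()]. NMR MODEL blocks populate
#' the chain's `models` list. The xyz dialect is one residue per line,
#' `index x y z`, whitespace separated, for generic polymers.
#'
#' Residues are renumbered 1-based sequentially (author numbering kept in
#' `resno`); for duplicated altLoc positions the highest-occupancy copy is
#' kept; HETATM-only chains are skipped. PDB/mmCIF chains with fewer than 4
#' CA atoms are skipped with a warning. Gaps in author numbering are
#' recorded but not yet modelled (see [model_gaps()]).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"cif"`, `"xyz"`; `"auto"` guesses
#'   from the file extension.
#' @return list of `lasso_chain` objects.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "cif", mmcif = "cif",
                     xyz = "xyz", txt = "xyz",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  switch(format,
         xyz = read_xyz(path),
         pdb = read_pdb_chains(path),
         cif = read_cif_chains(path))
}

read_xyz <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("index", "x", "y", "z"),
                           colClasses = c("integer", "numeric", "numeric", "numeric"))
  if (nrow(tab) < 1L) stop("empty xyz file: ", path)
  ord <- order(tab$index)
  tab <- tab[ord, , drop = FALSE]
  res <- data.frame(index = seq_len(nrow(tab)), resno = tab$index,
                    name = "UNK", x = tab$x, y = tab$y, z = tab$z,
                    bfactor = NA_real_, virtual = FALSE)
  gaps <- gaps_from_resno(res)
  list(new_chain("A", res, gaps = gaps))
}

# gap records from jumps in author numbering: start/end = flanking indices
gaps_from_resno <- function(res) {
  d <- diff(res$resno)
  at <- which(d > 1L)
  if (length(at) == 0L) return(empty_gaps())
  data.frame(start = res$index[at], end = res$index[at + 1L],
             n_missing = as.integer(d[at] - 1L), modeled = FALSE)
}

read_pdb_chains <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ", path,
                                           " (", conditionMessage(e), ")"))
  links <- scan_pdb_conn(path)
  chains_from_bio3d(pdb, links, min_ca = 4L)
}

read_cif_chains <- function(path) {
  pdb <- withCallingHandlers(
    tryCatch(bio3d::read.cif(path, verbose = FALSE),
             error = function(e) stop("unreadable mmCIF file: ", path,
                                      " (", conditionMessage(e), ")")),
    warning = function(w) {
      # bio3d's beta advisory, and annotation categories a coordinate-only
      # file legitimately lacks
      if (grepl("helix/sheet|beta version", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  links <- scan_cif_struct_conn(path)
  chains_from_bio3d(pdb, links, min_ca = 4L)
}

# shared conversion from a bio3d pdb object to lasso_chain list
chains_from_bio3d <- function(pdb, links, min_ca = 4L) {
  atom <- pdb$atom
  # highest-occupancy altLoc: keep best copy per (chain, resno, insert, atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  ord <- order(key, -occ)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]
  atom <- atom[order(as.integer(rownames(atom))), , drop = FALSE]

  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  chains <- list()
  for (ch in unique(atom$chain)) {
    sel <- atom$chain == ch & atom$type == "ATOM"
    if (!any(sel)) next                      # HETATM-only chain
    ca <- atom[sel & atom$elety == "CA", , drop = FALSE]
    if (nrow(ca) < min_ca) {
      warning("chain ", ch, " skipped: fewer than ", min_ca, " CA atoms")
      next
    }
    res <- data.frame(index = seq_len(nrow(ca)), resno = ca$resno,
                      name = ca$resid, x = ca$x, y = ca$y, z = ca$z,
                      bfactor = ca$b, virtual = FALSE)
    models <- NULL
    if (nmodels > 1L) {
      eleno_all <- as.integer(rownames(pdb$atom))
      rows <- match(as.integer(rownames(ca)), eleno_all)
      models <- lapply(seq_len(nmodels), function(m) {
        xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
        xyz[rows, , drop = FALSE]
      })
    }
    sc <- atom[sel & !(atom$elety %in% c("N", "CA", "C", "O")) &
                 !grepl("^H", atom$elety), , drop = FALSE]
    side <- if (nrow(sc) > 0) {
      idx <- match(paste(sc$resno, sc$insert), paste(ca$resno, ca$insert))
      keep <- !is.na(idx)
      data.frame(index = idx[keep], atom = sc$elety[keep],
                 x = sc$x[keep], y = sc$y[keep], z = sc$z[keep])
    } else empty_sidechain()
    ln <- links[links$chain_i == ch & links$chain_j == ch,
                c("resno_i", "atom_i", "resno_j", "atom_j", "rec")]
    chains[[length(chains) + 1L]] <-
      new_chain(ch, res, models = models, gaps = gaps_from_resno(res),
                sidechain = side, links = ln)
  }
  if (length(chains) == 0L) warning("no polymer chains found")
  chains
}

# SSBOND / LINK header records of a PDB file (fixed-column format)
scan_pdb_conn <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- data.frame(chain_i = character(), resno_i = integer(), atom_i = character(),
                    chain_j = character(), resno_j = integer(), atom_j = character(),
                    rec = character())
  ss <- lines[startsWith(lines, "SSBOND")]
  for (l in ss) {
    out[nrow(out) + 1L, ] <- list(substr(l, 16, 16), as.integer(substr(l, 18, 21)), "SG",
                                  substr(l, 30, 30), as.integer(substr(l, 32, 35)), "SG",
                                  "ssbond")
  }
  lk <- lines[startsWith(lines, "LINK")]
  for (l in lk) {
    out[nrow(out) + 1L, ] <- list(substr(l, 22, 22), as.integer(substr(l, 23, 26)),
                                  trimws(substr(l, 13, 16)),
                                  substr(l, 52, 52), as.integer(substr(l, 53, 56)),
                                  trimws(substr(l, 43, 46)),
                                  "link")
  }
  out
}

# minimal tolerant reader for the struct_conn category of an mmCIF file
scan_cif_struct_conn <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- data.frame(chain_i = character(), resno_i = integer(), atom_i = character(),
                    chain_j = character(), resno_j = integer(), atom_j = character(),
                    rec = character())
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L
      items <- character()
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        items <- c(items, trimws(lines[j])); j <- j + 1L
      }
      if (length(items) > 0 && all(startsWith(items, "_struct_conn."))) {
        fields <- sub("^_struct_conn\\.", "", items)
        while (j <= n) {
          l <- trimws(lines[j])
          if (l == "" || startsWith(l, "_") || startsWith(l, "loop_") ||
              startsWith(l, "#") || startsWith(l, "data_")) break
          tok <- scan(text = l, what = character(), quiet = TRUE)
          if (length(tok) == length(fields)) {
            v <- stats::setNames(tok, fields)
            type <- tolower(v[["conn_type_id"]])
            if (type %in% c("disulf", "covale")) {
              out[nrow(out) + 1L, ] <- list(
                v[["ptnr1_auth_asym_id"]] %||% v[["ptnr1_label_asym_id"]],
                as.integer(v[["ptnr1_auth_seq_id"]] %||% v[["ptnr1_label_seq_id"]]),
                v[["ptnr1_label_atom_id"]],
                v[["ptnr2_auth_asym_id"]] %||% v[["ptnr2_label_asym_id"]],
                as.integer(v[["ptnr2_auth_seq_id"]] %||% v[["ptnr2_label_seq_id"]]),
                v[["ptnr2_label_atom_id"]],
                "struct_conn")
            }
          }
          j <- j + 1L
        }
      }
      i <- j
    } else i <- i + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Model chain gaps as straight intervals
#'
#' For every recorded gap of g missing residues, g virtual residues are
#' placed equidistantly on the straight segment between the flanking CA
#' atoms, flagged `virtual = TRUE`, and the gap record is updated to the
#' inserted span. Idempotent: already-modelled gaps are left alone.
#'
#' @param chain a `lasso_chain` with at least 2 residues.
#' @return the chain with virtual residues inserted.
#' @export
model_gaps <- function(chain) {
  stopifnot(inherits(chain, "lasso_chain"), nrow(chain$residues) >= 2L)
  gaps <- chain$gaps
  todo <- which(!gaps$modeled)
  if (length(todo) == 0L) return(chain)
  res <- chain$residues
  models <- chain$models
  # insert from the last gap backwards so earlier indices stay valid
  for (k in rev(todo)) {
    i <- gaps$start[k]; j <- gaps$end[k]; g <- gaps$n_missing[k]
    p <- as.numeric(res[res$index == i, c("x", "y", "z")])
    q <- as.numeric(res[res$index == j, c("x", "y", "z")])
    t <- seq_len(g) / (g + 1)
    virt <- data.frame(index = 0L,
                       resno = res$resno[res$index == i] + seq_len(g),
                       name = "UNK",
                       x = p[1] + t * (q[1] - p[1]),
                       y = p[2] + t * (q[2] - p[2]),
                       z = p[3] + t * (q[3] - p[3]),
                       bfactor = NA_real_, virtual = TRUE)
    pos <- which(res$index == i)
    res <- rbind(res[seq_len(pos), ], virt, res[(pos + 1L):nrow(res), ])
    if (!is.null(models)) {
      models <- lapply(models, function(m) {
        pm <- m[i, ]; qm <- m[j, ]
        vm <- cbind(pm[1] + t * (qm[1] - pm[1]),
                    pm[2] + t * (qm[2] - pm[2]),
                    pm[3] + t * (qm[3] - pm[3]))
        rbind(m[seq_len(i), , drop = FALSE], vm,
              m[(i + 1L):nrow(m), , drop = FALSE])
      })
    }
    # shift bookkeeping of other gaps and sidechain indices
    shift <- function(v) ifelse(v > i, v + g, v)
    gaps$start <- shift(gaps$start); gaps$end <- shift(gaps$end)
    chain$sidechain$index <- shift(chain$sidechain$index)
    gaps$start[k] <- i + 1L; gaps$end[k] <- i + g; gaps$modeled[k] <- TRUE
  }
  res$index <- seq_len(nrow(res))
  chain$residues <- res
  chain$models <- models
  chain$gaps <- gaps
  chain
}

#' Detect loop-closing bridges
#'
#' Disulfides are detected geometrically as CYS SG-SG pairs within
#' `max_ss_dist`. Non-disulfide bridges (amide/amine, ester/ether,
#' thioester/thioether, C-C) are accepted only from explicit LINK /
#' `struct_conn` / SSBOND records between side-chain atoms of two residues of
#' the same chain -- many distance-plausible candidates in deposited files
#' are artificial -- unless `permissive = TRUE`, which additionally accepts
#' heavy-atom side-chain contacts at or below `permissive_dist`. Bonds
#' between sequence-adjacent residues (peptide bonds) are excluded.
#'
#' @param chain a `lasso_chain`.
#' @param max_ss_dist geometric SG-SG threshold in Angstrom (default 2.5;
#'   a covalent S-S bond is about 2.05, the margin absorbs poor models).
#' @param use_links honour bond records read from the file (default TRUE).
#' @param permissive enable distance-based non-disulfide detection.
#' @param permissive_dist heavy-atom threshold for `permissive` (default 1.8).
#' @return data.frame with columns `res_i`, `res_j`, `chemistry`, `source`.
#' @export
detect_bridges <- function(chain, max_ss_dist = 2.5, use_links = TRUE,
                           permissive = FALSE, permissive_dist = 1.8) {
  res_i <- integer(); res_j <- integer()
  chem <- character(); src <- character()
  sc <- chain$sidechain
  cys <- chain$residues$index[chain$residues$name == "CYS"]
  sg <- sc[sc$atom == "SG" & sc$index %in% cys, , drop = FALSE]
  if (nrow(sg) >= 2L) {
    for (a in seq_len(nrow(sg) - 1L)) for (b in (a + 1L):nrow(sg)) {
      ia <- sg$index[a]; ib <- sg$index[b]
      if (abs(ia - ib) <= 1L) next
      d <- vnorm(c(sg$x[a] - sg$x[b], sg$y[a] - sg$y[b], sg$z[a] - sg$z[b]))
      if (d <= max_ss_dist) {
        res_i <- c(res_i, ia); res_j <- c(res_j, ib)
        chem <- c(chem, "disulfide"); src <- c(src, "geometry")
      }
    }
  }
  if (use_links && nrow(chain$links) > 0) {
    for (k in seq_len(nrow(chain$links))) {
      ln <- chain$links[k, ]
      ia <- chain$residues$index[match(ln$resno_i, chain$residues$resno)]
      ib <- chain$residues$index[match(ln$resno_j, chain$residues$resno)]
      if (is.na(ia) || is.na(ib)) {
        warning("bond record names residue absent from chain ", chain$id,
                " (", ln$resno_i, "-", ln$resno_j, "): dropped")
        next
      }
      if (abs(ia - ib) <= 1L) next
      chemk <- if (ln$rec == "ssbond") "disulfide" else
        link_chemistry(ln$atom_i, ln$atom_j, chain$residues$name[c(ia, ib)])
      res_i <- c(res_i, ia); res_j <- c(res_j, ib)
      chem <- c(chem, chemk); src <- c(src, "link_record")
    }
  }
  if (permissive && nrow(sc) >= 2L) {
    for (a in seq_len(nrow(sc) - 1L)) for (b in (a + 1L):nrow(sc)) {
      ia <- sc$index[a]; ib <- sc$index[b]
      if (abs(ia - ib) <= 1L) next
      d <- vnorm(c(sc$x[a] - sc$x[b], sc$y[a] - sc$y[b], sc$z[a] - sc$z[b]))
      if (d <= permissive_dist) {
        res_i <- c(res_i, ia); res_j <- c(res_j, ib)
        chem <- c(chem, link_chemistry(sc$atom[a], sc$atom[b],
                                       chain$residues$name[c(ia, ib)]))
        src <- c(src, "geometry")
      }
    }
  }
  br <- new_bridges(res_i, res_j, chem, src)
  br[!duplicated(br[, c("res_i", "res_j")]), , drop = FALSE]
}

# chemistry from the element pair of two bonded atoms:
# N-C -> amide/amine, C-O -> ester/ether, C-S -> thioester/thioether, C-C -> CC
link_chemistry <- function(atom_i, atom_j, resnames) {
  el <- function(a) substr(a, 1L, 1L)
  e <- sort(c(el(atom_i), el(atom_j)))
  # carbonyl-like carbon: backbone C or the acyl carbon of D/E/N/Q side chains
  carbonylish <- function(a, rn) {
    el(a) == "C" && (a == "C" || rn %in% c("ASP", "GLU", "ASN", "GLN"))
  }
  has_carbonyl <- carbonylish(atom_i, resnames[1L]) ||
    carbonylish(atom_j, resnames[2L])
  if (identical(e, c("S", "S"))) return("disulfide")
  if (identical(e, c("C", "N"))) return(if (has_carbonyl) "amide" else "amine")
  if (identical(e, c("C", "O"))) return(if (has_carbonyl) "ester" else "ether")
  if (identical(e, c("C", "S"))) return(if (has_carbonyl) "thioester" else "thioether")
  if (identical(e, c("C", "C"))) return("CC")
  "other"
}

#' Structure validity test for a covalent loop
#'
#' A loop is classified `artifact` when its topology cannot be trusted:
#' a modelled-in gap of more than `max_loop_gap` missing residues lies
#' inside the loop span; any gap lies within 3 residues of a detected
#' piercing segment (pass the piercing table for this post-hoc check); a
#' bridge atom named by a bond record is missing although side-chain atoms
#' were read; or the chain is shorter than 4 residues.
#'
#' @param chain a gap-modelled `lasso_chain`.
#' @param loop a `lasso_loop`.
#' @param max_loop_gap largest tolerated in-loop gap, residues (default 2).
#' @param piercings optional piercing table from [reduce_crossings()].
#' @return list with `status` (`"certain"` or `"artifact"`) and `reasons`.
#' @export
validate_loop <- function(chain, loop, max_loop_gap = 2L, piercings = NULL) {
  reasons <- character()
  if (nrow(chain$residues) < 4L) reasons <- c(reasons, "chain-too-short")
  g <- chain$gaps
  if (nrow(g) > 0) {
    gs <- ifelse(g$modeled, g$start, g$start)      # first index touched by gap
    ge <- ifelse(g$modeled, g$end, g$end)
    in_loop <- gs <= loop$res_j & ge >= loop$res_i
    if (any(in_loop & g$n_missing > max_loop_gap))
      reasons <- c(reasons, "gap-in-loop")
    if (!is.null(piercings) && nrow(piercings) > 0) {
      for (k in seq_len(nrow(piercings))) {
        seg <- range(piercings$seg_from[k], piercings$seg_to[k])
        near <- gs <= seg[2L] + 3L & ge >= seg[1L] - 3L
        if (any(near)) { reasons <- c(reasons, "gap-near-piercing"); break }
      }
    }
  }
  if (loop$bridge$source == "link_record" && nrow(chain$sidechain) > 0) {
    have <- c(any(chain$sidechain$index == loop$res_i),
              any(chain$sidechain$index == loop$res_j))
    if (!all(have)) reasons <- c(reasons, "missing-bridge-atom")
  }
  reasons <- unique(reasons)
  list(status = if (length(reasons)) "artifact" else "certain",
       reasons = reasons)
}

#' Write a loop/bridge table as TSV
#'
#' @param chains list of `lasso_chain` objects (or a single chain).
#' @param path output file.
#' @param ... passed to [detect_bridges()].
#' @return the table, invisibly.
#' @export
write_loop_table <- function(chains, path, ...) {
  if (inherits(chains, "lasso_chain")) chains <- list(chains)
  rows <- lapply(chains, function(ch) {
    ch <- model_gaps(ch)
    br <- detect_bridges(ch, ...)
    loops <- extract_loops(ch, br)
    if (length(loops) == 0L) return(NULL)
    do.call(rbind, lapply(loops, function(lp) {
      v <- validate_loop(ch, lp)
      data.frame(chain = ch$id, res_i = lp$res_i, res_j = lp$res_j,
                 chemistry = lp$bridge$chemistry, status = v$status)
    }))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(chain = character(), res_i = integer(), res_j = integer(),
                      chemistry = character(), status = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
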