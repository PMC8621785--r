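test_that("xyz files parse as one chain with gaps from index jumps", {
  f <- write_tmp(c("1 0 0 0", "2 1 0 0", "3 2 0 0"), ".xyz")
  chains <- read_structure(f, "xyz")
  expect_length(chains, 1L)
  expect_equal(nrow(chains[[1L]]$residues), 3L)
  expect_equal(chains[[1L]]$residues$x, c(0, 1, 2))
  # author numbering 10,11,15: gap of 3 between consecutive indices 2 and 3
  f2 <- write_tmp(c("10 0 0 0", "11 0 0 3", "15 0 0 15"), ".xyz")
  ch <- read_structure(f2, "xyz")[[1L]]
  expect_equal(nrow(ch$gaps), 1L)
  expect_equal(ch$gaps$n_missing, 3L)
  expect_equal(ch$gaps[, c("start", "end")], data.frame(start = 2L, end = 3L))
})

test_that("PDB files parse residues, B-factors, models and SSBOND records", {
  lines <- make_pdb_text(1:8, cys_at = c(2L, 6L),
                         sg_xyz = rbind(c(7, 1, 0), c(8, 1, 0)))
  lines <- c("SSBOND   1 CYS A    2    CYS A    6", lines)
  ch <- read_structure(write_tmp(lines, ".pdb"))[[1L]]
  expect_equal(nrow(ch$residues), 8L)
  expect_identical(ch$residues$name[2L], "CYS")
  expect_equal(ch$residues$bfactor, rep(10, 8))
  expect_equal(nrow(ch$links), 1L)
  expect_identical(ch$links$rec, "ssbond")
  # multi-model file: models with equal residue lists
  ml <- make_pdb_text(1:6, models = 2L, model_shift = 1.5)
  ch2 <- read_structure(write_tmp(ml, ".pdb"))[[1L]]
  expect_length(ch2$models, 2L)
  expect_equal(dim(ch2$models[[1L]]), dim(ch2$models[[2L]]))
  expect_equal(ch2$models[[2L]][, 3] - ch2$models[[1L]][, 3], rep(1.5, 6))
  # numbering 10,11,15 records a gap
  g <- read_structure(write_tmp(make_pdb_text(c(10:11, 15:18)), ".pdb"))[[1L]]
  expect_equal(g$gaps$n_missing, 3L)
  expect_error(read_structure(tempfile(), "pdb"), "cannot read")
})

test_that("chains shorter than 4 CA are skipped with a warning", {
  lines <- make_pdb_text(1:3)
  w <- capture_warnings(chains <- read_structure(write_tmp(lines, ".pdb")))
  expect_match(w, "fewer than 4", all = FALSE)
  expect_length(chains, 0L)
})

test_that("gap modelling interpolates straight equidistant virtual residues", {
  res <- data.frame(index = 1:2, resno = c(5L, 7L), name = "GLY",
                    x = 0, y = 0, z = c(0, 3), bfactor = NA_real_, virtual = FALSE)
  ch <- new_chain("A", res, gaps = data.frame(start = 1L, end = 2L,
                                              n_missing = 1L, modeled = FALSE))
  m <- model_gaps(ch)
  expect_equal(nrow(m$residues), 3L)
  expect_equal(m$residues$z, c(0, 1.5, 3))
  expect_identical(m$residues$virtual, c(FALSE, TRUE, FALSE))
  # no gaps: unchanged
  ch0 <- new_chain("A", transform(res, resno = 1:2))
  expect_identical(model_gaps(ch0), ch0)
  # gap of 3 between (0,0,0) and (4,0,0): x = 1,2,3
  res3 <- data.frame(index = 1:2, resno = c(1L, 5L), name = "GLY",
                     x = c(0, 4), y = 0, z = 0, bfactor = NA_real_, virtual = FALSE)
  ch3 <- new_chain("A", res3, gaps = data.frame(start = 1L, end = 2L,
                                                n_missing = 3L, modeled = FALSE))
  m3 <- model_gaps(ch3)
  expect_equal(m3$residues$x, c(0, 1, 2, 3, 4))
  # idempotent
  expect_identical(model_gaps(m3), m3)
  # consecutive CA distance after modelling is bonded-scale
  expect_true(all(abs(diff(m3$residues$x)) <= 4.3))
})

test_that("geometric disulfide detection honours the SG-SG threshold", {
  mk <- function(d) {
    res <- data.frame(index = 1:8, resno = 1:8, name = ifelse(1:8 %in% c(2, 6), "CYS", "GLY"),
                      x = (1:8) * 3.8, y = 0, z = 0, bfactor = NA_real_, virtual = FALSE)
    sc <- data.frame(index = c(2L, 6L), atom = "SG",
                     x = c(0, d), y = 1, z = 0)
    new_chain("A", res, sidechain = sc)
  }
  br <- detect_bridges(mk(2.05))
  expect_equal(nrow(br), 1L)
  expect_identical(br$chemistry, "disulfide")
  expect_identical(br$source, "geometry")
  expect_equal(nrow(detect_bridges(mk(4.0))), 0L)
  # symmetric in atom order and rigid-motion invariant
  ch <- mk(2.05)
  ch$sidechain <- ch$sidechain[2:1, ]
  expect_equal(detect_bridges(ch)[, c("res_i", "res_j")],
               br[, c("res_i", "res_j")], ignore_attr = TRUE)
  set.seed(2)
  Rm <- random_rotation()
  mv <- transform_chain(mk(2.05), Rm, shift = c(3, -4, 7))
  sc <- as.matrix(mk(2.05)$sidechain[, c("x", "y", "z")])
  mv$sidechain[, c("x", "y", "z")] <- sweep(sc %*% t(Rm), 2L, c(3, -4, 7), `+`)
  expect_equal(detect_bridges(mv)$res_i, br$res_i)
})

test_that("LINK records yield chemistry-typed bridges; adjacent and broken ones drop", {
  res <- data.frame(index = 1:10, resno = 1:10, name = "GLY", x = (1:10) * 3.8,
                    y = 0, z = 0, bfactor = NA_real_, virtual = FALSE)
  links <- data.frame(resno_i = 2L, atom_i = "NZ", resno_j = 9L, atom_j = "C",
                      rec = "link")
  ch <- new_chain("A", res, links = links)
  br <- detect_bridges(ch)
  expect_identical(br$chemistry, "amide")     # side-chain N to backbone C
  expect_identical(br$source, "link_record")
  # ester and thioester chemistry from element pairs
  ch$links <- data.frame(resno_i = 2L, atom_i = "OG", resno_j = 9L, atom_j = "CG",
                         rec = "link")
  ch$residues$name[9L] <- "ASP"
  expect_identical(detect_bridges(ch)$chemistry, "ester")
  ch$links <- data.frame(resno_i = 2L, atom_i = "SG", resno_j = 9L, atom_j = "CD",
                         rec = "link")
  ch$residues$name[9L] <- "GLN"
  expect_identical(detect_bridges(ch)$chemistry, "thioester")
  ch$links <- data.frame(resno_i = 2L, atom_i = "CE", resno_j = 9L, atom_j = "CZ",
                         rec = "link")
  ch$residues$name[9L] <- "GLY"
  expect_identical(detect_bridges(ch)$chemistry, "CC")
  # sequence-adjacent bond excluded; missing residue dropped with warning
  ch$links <- data.frame(resno_i = 4L, atom_i = "NZ", resno_j = 5L, atom_j = "C",
                         rec = "link")
  expect_equal(nrow(detect_bridges(ch)), 0L)
  ch$links <- data.frame(resno_i = 2L, atom_i = "NZ", resno_j = 99L, atom_j = "C",
                         rec = "link")
  expect_warning(br2 <- detect_bridges(ch), "dropped")
  expect_equal(nrow(br2), 0L)
})

test_that("loops are extracted per bridge with tails and short spans omitted", {
  res <- data.frame(index = 1:50, resno = 1:50, name = "GLY", x = (1:50) * 3.8,
                    y = 0, z = 0, bfactor = NA_real_, virtual = FALSE)
  ch <- new_chain("A", res)
  br <- lassotopo:::new_bridges(c(10L, 35L, 5L), c(30L, 45L, 7L),
                                rep("disulfide", 3), rep("geometry", 3))
  loops <- extract_loops(ch, br)
  expect_length(loops, 2L)
  expect_equal(loops[[1L]]$span, 10:30)
  expect_equal(loops[[1L]]$n_tail, 1:9)
  expect_equal(loops[[1L]]$c_tail, 31:50)
  expect_equal(loops[[2L]]$res_i, 35L)
  om <- attr(loops, "omitted")
  expect_length(om, 1L)
  expect_identical(om[[1L]]$reason, "span-too-short")
})

test_that("the validity test flags large in-loop gaps but tolerates small ones", {
  res <- data.frame(index = 1:40, resno = 1:40, name = "GLY", x = (1:40) * 3.8,
                    y = 0, z = 0, bfactor = NA_real_, virtual = FALSE)
  mkch <- function(gaps = empty_gaps()) new_chain("A", res, gaps = gaps)
  br <- lassotopo:::new_bridges(10L, 30L, "disulfide", "geometry")
  loop <- extract_loops(mkch(), br)[[1L]]
  # gap-free chain is certain
  expect_identical(validate_loop(mkch(), loop)$status, "certain")
  # gap of 5 inside the loop span -> artifact
  g5 <- data.frame(start = 15L, end = 19L, n_missing = 5L, modeled = TRUE)
  v <- validate_loop(mkch(g5), loop)
  expect_identical(v$status, "artifact")
  expect_true("gap-in-loop" %in% v$reasons)
  # gap of 1 inside the loop -> still certain (within max_loop_gap)
  g1 <- data.frame(start = 15L, end = 15L, n_missing = 1L, modeled = TRUE)
  expect_identical(validate_loop(mkch(g1), loop)$status, "certain")
  # any gap within 3 residues of a piercing segment -> artifact
  p <- data.frame(tail = "C", seg_from = 33L, seg_to = 34L, sign = 1L,
                  t = 0.5, x = 0, y = 0, z = 0, depth = 7L, rank = 1L)
  gnear <- data.frame(start = 36L, end = 36L, n_missing = 1L, modeled = TRUE)
  vn <- validate_loop(mkch(gnear), loop, piercings = p)
  expect_identical(vn$status, "artifact")
  expect_true("gap-near-piercing" %in% vn$reasons)
})

test_that("mmCIF atom_site and struct_conn records are read", {
  hdr <- c("data_test", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  row <- function(id, resno, x)
    sprintf("ATOM %d C CA . GLY A 1 %d ? %.3f 0.000 0.000 1.00 10.00 ? %d GLY A CA 1",
            id, resno, x, resno)
  conn <- c("#", "loop_",
            paste0("_struct_conn.",
                   c("id", "conn_type_id", "ptnr1_auth_asym_id",
                     "ptnr1_auth_seq_id", "ptnr1_label_atom_id",
                     "ptnr2_auth_asym_id", "ptnr2_auth_seq_id",
                     "ptnr2_label_atom_id")),
            "covale1 covale A 1 NZ A 5 C", "#")
  f <- write_tmp(c(hdr, vapply(1:5, function(i) row(i, i, i * 3.5),
                               character(1L)), conn), ".cif")
  ch <- read_structure(f, "cif")[[1L]]
  expect_equal(nrow(ch$residues), 5L)
  expect_equal(nrow(ch$links), 1L)
  br <- detect_bridges(ch)
  expect_identical(br$chemistry, "amide")
  expect_equal(br$res_j - br$res_i, 4L)
})

test_that("the loop/bridge TSV export lists chain, span, chemistry and status", {
  fx <- make_lasso_fixture("L-1C")
  f <- tempfile(fileext = ".pdb")
  write_ca_pdb(fx$chain, f, fx$bridges)
  out <- tempfile(fileext = ".tsv")
  tab <- write_loop_table(read_structure(f), out)
  expect_true(file.exists(out))
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$chemistry, "disulfide")
  expect_identical(tab$status, "certain")
  back <- utils::read.delim(out)
  expect_equal(back$res_i, tab$res_i)
})
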