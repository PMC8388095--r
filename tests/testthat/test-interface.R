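# Interface extraction: pose selection, contacts, charge classes, cofactors.

test_that("charge classification partitions the standard residues", {
  expect_equal(classify_residue("ASP"), "negative")
  expect_equal(classify_residue("GLU"), "negative")
  expect_equal(classify_residue(c("LYS", "ARG", "HIS")),
               rep("positive", 3))
  expect_equal(classify_residue(c("SER", "TYR")), rep("neutral", 2))
  expect_equal(classify_residue(c("LEU", "GLY", "CYS")),
               rep("hydrophobic", 3))
  aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
  cls <- classify_residue(aa20)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls),
                  c("negative", "positive", "neutral", "hydrophobic"))
  expect_warning(cls_x <- classify_residue("XXX"), "unknown")
  expect_equal(cls_x, "neutral")
})

test_that("select_top_poses implements both selection modes", {
  poses <- data.frame(tx = seq(0, 90, 10), ty = 0, tz = 0,
                      qw = 1, qx = 0, qy = 0, qz = 0, energy = 0:9, run = 1L)
  ens <- structure(list(poses = poses, config = NULL,
                        receptor_com = c(0, 0, 0)), class = "PoseEnsemble")
  # identity at fraction 1
  expect_equal(nrow(select_top_poses(ens, "lowest_energy", 1)$poses), 10)
  # bottom 20% by energy
  sel <- select_top_poses(ens, "lowest_energy", 0.2)
  expect_setequal(sel$poses$energy, c(0, 1))
  # densest voxels: duplicate one position so its voxel dominates
  poses2 <- poses
  poses2$tx[1:5] <- 1   # five poses share a voxel
  ens2 <- ens; ens2$poses <- poses2
  sel2 <- select_top_poses(ens2, "densest_voxels", 0.4, spacing = 2)
  expect_true(all(sel2$poses$tx == 1))
  expect_equal(nrow(sel2$poses), 5)
  empty <- ens; empty$poses <- poses[0, ]
  expect_error(select_top_poses(empty, "lowest_energy", 0.5), "empty")
})

test_that("contact_residues counts touching residues with correct frequencies", {
  # receptor: two single-atom residues 10 A apart + one buried cofactor
  at <- data.frame(serial = 1:3, name = c("CA", "CA", "FE"),
                   resname = c("ASP", "LYS", "HEC"),
                   resid = c(1L, 2L, 3L), chain = "A",
                   x = c(0, 10, 50), y = 0, z = 0,
                   charge = 0, radius = 1.5,
                   cofactor_id = c(NA, NA, "heme3"))
  rec <- molecular_model(at)
  lig <- probe_ligand(0)
  # one pose at 4.9 A from residue 1 only
  mk_ens <- function(df) structure(list(poses = df, receptor_com = c(0, 0, 0)),
                                   class = "PoseEnsemble")
  p1 <- data.frame(tx = 0, ty = 4.9, tz = 0, qw = 1, qx = 0, qy = 0, qz = 0,
                   energy = 0, run = 1L)
  rep1 <- contact_residues(rec, lig, mk_ens(p1), cutoff = 5)
  expect_equal(nrow(rep1$entries), 1L)
  expect_equal(rep1$entries$resid, 1L)
  expect_equal(rep1$entries$contact_frequency, 1)
  expect_equal(rep1$entries$charge_class, "negative")
  # two poses, second touching residue 2 as well -> frequencies 0.5/0.5
  p2 <- rbind(p1, data.frame(tx = 10, ty = 3, tz = 0, qw = 1, qx = 0,
                             qy = 0, qz = 0, energy = 0, run = 1L))
  rep2 <- contact_residues(rec, lig, mk_ens(p2), cutoff = 5)
  expect_equal(sort(rep2$entries$contact_frequency), c(0.5, 0.5))
  # far ligand -> empty report
  pf <- p1; pf$ty <- 500
  rep3 <- contact_residues(rec, lig, mk_ens(pf), cutoff = 5)
  expect_equal(nrow(rep3$entries), 0L)
  expect_equal(rep3$cofactor_hits$contact_frequency, 0)
  # frequencies invariant under pose order permutation
  rep4 <- contact_residues(rec, lig, mk_ens(p2[2:1, ]), cutoff = 5)
  expect_equal(rep4$entries[order(rep4$entries$resid), ],
               rep2$entries[order(rep2$entries$resid), ],
               ignore_attr = TRUE)
})

test_that("cofactor_in_interface applies the frequency threshold", {
  s <- specificity_system()
  ens <- specificity_ensembles()
  top <- select_top_poses(ens$neg, "lowest_energy", 0.1)
  rep <- contact_residues(s$rec, s$lig_neg, top)
  in3 <- cofactor_in_interface(rep, "heme3", 0.25)
  in1 <- cofactor_in_interface(rep, "heme1", 0.25)
  expect_true(in3)
  expect_false(in1)
  expect_lt(attr(in3, "min_dist"), attr(in1, "min_dist"))
  # threshold 0 flags any contact at all
  expect_true(cofactor_in_interface(rep, "heme3", 0))
  expect_error(cofactor_in_interface(rep, "hemeZ"), "unknown cofactor")
})

test_that("patch residues dominate the synthetic interface report", {
  s <- specificity_system()
  ens <- specificity_ensembles()
  top <- select_top_poses(ens$neg, "lowest_energy", 0.1)
  rep <- contact_residues(s$rec, s$lig_neg, top)
  # classes of reported residues partition the report (no NA, all 4 levels
  # possible)
  expect_false(anyNA(rep$entries$charge_class))
  expect_true(all(rep$entries$charge_class %in%
                    c("negative", "positive", "neutral", "hydrophobic")))
  # frequencies sorted descending and inside [0, 1]
  expect_true(all(diff(rep$entries$contact_frequency) <= 0))
  expect_true(all(rep$entries$contact_frequency >= 0 &
                    rep$entries$contact_frequency <= 1))
  # the most frequent contacts are patch (positive) residues
  expect_true(all(head(rep$entries$resid, 5) %in% s$patch_resids))
  # both selection modes place the top poses over the patch
  for (mode in c("lowest_energy", "densest_voxels")) {
    sel <- select_top_poses(ens$neg, mode, 0.1)
    proj <- as.matrix(sel$poses[, c("tx", "ty", "tz")]) %*% s$patch_axis
    expect_gt(mean(proj > 0), 0.95)
  }
})
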