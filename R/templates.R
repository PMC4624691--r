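## Internal template tables: per-element properties and ideal side-chain
## geometries used to graft mutated residues and labels onto a host
## backbone.  Values are generic ideal bond lengths/angles; the package
## is a restraint/exclusion layer, not a force field, so these only need
## to produce reasonable desk-scale geometry.

.elementTable <- data.frame(
  element  = c("H", "C", "N", "O", "S", "CD", "MG", "ZN", "X"),
  mass     = c(1.008, 12.011, 14.007, 15.999, 32.06,
               112.411, 24.305, 65.38, 72.0),
  epsilon  = c(0.03, 0.07, 0.20, 0.12, 0.45, 0.12, 0.015, 0.25, 0.10),
  rminHalf = c(1.34, 2.00, 1.85, 1.70, 2.00, 1.37, 1.19, 1.09, 2.20),
  stringsAsFactors = FALSE
)

.ionResnames <- c(CD = "CD", MG = "MG", ZN = "ZN")

## Infer the element from an atom name (and residue name for ions /
## pseudo-atoms).  PDB atom names lead with the element once digits are
## stripped; two-letter ion names are disambiguated by residue name.
.inferElement <- function(name, resname = "") {
  name <- toupper(trimws(name))
  resname <- toupper(trimws(resname))
  if (resname %in% names(.ionResnames) && name %in% names(.ionResnames))
    return(name)
  if (name == "DU" || resname == "DUM") return("X")
  stripped <- gsub("[0-9']", "", name)
  first <- substr(stripped, 1L, 1L)
  if (first %in% .elementTable$element) first else "C"
}

.elementProps <- function(element) {
  i <- match(element, .elementTable$element)
  i[is.na(i)] <- match("C", .elementTable$element)
  .elementTable[i, , drop = FALSE]
}

## Side-chain templates.  Atom placement rows are NeRF internal
## coordinates: the atom is placed `bond` Angstrom from refC, with angle
## atom-refC-refB and dihedral atom-refC-refB-refA (degrees).  Backbone
## atoms N, CA, C, O are available as references.
.tplAtom <- function(name, element, charge, refA, refB, refC,
                     bond, angle, dihedral) {
  data.frame(name = name, element = element, charge = charge,
             refA = refA, refB = refB, refC = refC,
             bond = bond, angle = angle, dihedral = dihedral,
             stringsAsFactors = FALSE)
}

.tplBond <- function(a, b, k, b0)
  data.frame(a = a, b = b, k = k, b0 = b0, stringsAsFactors = FALSE)

.tplAngle <- function(a, b, c, k, theta0)
  data.frame(a = a, b = b, c = c, k = k, theta0 = theta0,
             stringsAsFactors = FALSE)

.tplDihedral <- function(a, b, c, d, k, mult, delta)
  data.frame(a = a, b = b, c = c, d = d, k = k, mult = mult,
             delta = delta, stringsAsFactors = FALSE)

.backboneBonds <- rbind(
  .tplBond("N", "CA", 300, 1.458),
  .tplBond("CA", "C", 300, 1.525),
  .tplBond("C", "O", 500, 1.231)
)

.backboneAngles <- rbind(
  .tplAngle("N", "CA", "C", 50, 111.2),
  .tplAngle("CA", "C", "O", 50, 120.5)
)

.sideChainTemplates <- list(

  ## deprotonated cysteine (thiolate, net -1) for Cd2+ bridges
  CYS = list(
    charge = -1,
    atoms = rbind(
      .tplAtom("CB", "C", 0.0, "N", "C", "CA", 1.530, 110.6, 122.6),
      .tplAtom("SG", "S", -1.0, "N", "CA", "CB", 1.820, 114.4, -60.0)
    ),
    bonds = rbind(
      .tplBond("CA", "CB", 250, 1.530),
      .tplBond("CB", "SG", 200, 1.820)
    ),
    angles = rbind(
      .tplAngle("N", "CA", "CB", 50, 110.5),
      .tplAngle("C", "CA", "CB", 50, 110.6),
      .tplAngle("CA", "CB", "SG", 50, 114.4)
    ),
    dihedrals = .tplDihedral("N", "CA", "CB", "SG", 0.3, 3L, 0),
    chiBonds = list(c("CA", "CB")),
    coordAtom = "SG",
    reach = 2.9
  ),

  ## deprotonated aspartate (net -1) for Mg2+ bridges; Mg coordinates OD2
  ASP = list(
    charge = -1,
    atoms = rbind(
      .tplAtom("CB", "C", 0.0, "N", "C", "CA", 1.530, 110.6, 122.6),
      .tplAtom("CG", "C", 0.0, "N", "CA", "CB", 1.520, 112.6, -60.0),
      .tplAtom("OD1", "O", -0.5, "CA", "CB", "CG", 1.250, 118.3, 0.0),
      .tplAtom("OD2", "O", -0.5, "CA", "CB", "CG", 1.250, 118.3, 180.0)
    ),
    bonds = rbind(
      .tplBond("CA", "CB", 250, 1.530),
      .tplBond("CB", "CG", 250, 1.520),
      .tplBond("CG", "OD1", 400, 1.250),
      .tplBond("CG", "OD2", 400, 1.250)
    ),
    angles = rbind(
      .tplAngle("N", "CA", "CB", 50, 110.5),
      .tplAngle("CA", "CB", "CG", 50, 112.6),
      .tplAngle("CB", "CG", "OD1", 60, 118.3),
      .tplAngle("CB", "CG", "OD2", 60, 118.3),
      .tplAngle("OD1", "CG", "OD2", 60, 123.4)
    ),
    dihedrals = .tplDihedral("N", "CA", "CB", "CG", 0.3, 3L, 0),
    chiBonds = list(c("CA", "CB"), c("CB", "CG")),
    coordAtom = "OD2",
    reach = 3.7
  ),

  ## deprotonated histidine (imidazolate, net -1) for Zn2+ bridges;
  ## Zn coordinates NE2
  HIS = list(
    charge = -1,
    atoms = rbind(
      .tplAtom("CB", "C", 0.0, "N", "C", "CA", 1.530, 110.6, 122.6),
      .tplAtom("CG", "C", 0.0, "N", "CA", "CB", 1.500, 113.8, -60.0),
      .tplAtom("ND1", "N", -0.5, "CA", "CB", "CG", 1.380, 122.5, 90.0),
      .tplAtom("CD2", "C", 0.0, "CA", "CB", "CG", 1.360, 129.1, -90.0),
      .tplAtom("CE1", "C", 0.0, "CB", "CG", "ND1", 1.320, 108.0, 180.0),
      .tplAtom("NE2", "N", -0.5, "CB", "CG", "CD2", 1.370, 107.2, 180.0)
    ),
    bonds = rbind(
      .tplBond("CA", "CB", 250, 1.530),
      .tplBond("CB", "CG", 250, 1.500),
      .tplBond("CG", "ND1", 350, 1.380),
      .tplBond("CG", "CD2", 350, 1.360),
      .tplBond("ND1", "CE1", 350, 1.320),
      .tplBond("CD2", "NE2", 350, 1.370),
      .tplBond("CE1", "NE2", 350, 1.320)
    ),
    angles = rbind(
      .tplAngle("N", "CA", "CB", 50, 110.5),
      .tplAngle("CA", "CB", "CG", 50, 113.8),
      .tplAngle("CB", "CG", "ND1", 50, 122.5),
      .tplAngle("CB", "CG", "CD2", 50, 129.1),
      .tplAngle("CG", "ND1", "CE1", 70, 108.0),
      .tplAngle("CG", "CD2", "NE2", 70, 107.2),
      .tplAngle("ND1", "CE1", "NE2", 70, 110.0),
      .tplAngle("CD2", "NE2", "CE1", 70, 107.5)
    ),
    dihedrals = rbind(
      .tplDihedral("N", "CA", "CB", "CG", 0.3, 3L, 0),
      .tplDihedral("CB", "CG", "ND1", "CE1", 2.0, 2L, 180),
      .tplDihedral("CB", "CG", "CD2", "NE2", 2.0, 2L, 180)
    ),
    chiBonds = list(c("CA", "CB"), c("CB", "CG")),
    coordAtom = "NE2",
    reach = 4.7
  ),

  ## lysine (net +1): salt-bridge donor, NZ restrained to the acceptor
  LYS = list(
    charge = 1,
    atoms = rbind(
      .tplAtom("CB", "C", 0.0, "N", "C", "CA", 1.530, 110.6, 122.6),
      .tplAtom("CG", "C", 0.0, "N", "CA", "CB", 1.520, 114.1, -60.0),
      .tplAtom("CD", "C", 0.0, "CA", "CB", "CG", 1.520, 111.3, 180.0),
      .tplAtom("CE", "C", 0.0, "CB", "CG", "CD", 1.520, 111.3, 180.0),
      .tplAtom("NZ", "N", 1.0, "CG", "CD", "CE", 1.490, 111.5, 180.0)
    ),
    bonds = rbind(
      .tplBond("CA", "CB", 250, 1.530),
      .tplBond("CB", "CG", 250, 1.520),
      .tplBond("CG", "CD", 250, 1.520),
      .tplBond("CD", "CE", 250, 1.520),
      .tplBond("CE", "NZ", 250, 1.490)
    ),
    angles = rbind(
      .tplAngle("N", "CA", "CB", 50, 110.5),
      .tplAngle("CA", "CB", "CG", 50, 114.1),
      .tplAngle("CB", "CG", "CD", 50, 111.3),
      .tplAngle("CG", "CD", "CE", 50, 111.3),
      .tplAngle("CD", "CE", "NZ", 50, 111.5)
    ),
    dihedrals = rbind(
      .tplDihedral("N", "CA", "CB", "CG", 0.3, 3L, 0),
      .tplDihedral("CA", "CB", "CG", "CD", 0.3, 3L, 0),
      .tplDihedral("CB", "CG", "CD", "CE", 0.3, 3L, 0),
      .tplDihedral("CG", "CD", "CE", "NZ", 0.3, 3L, 0)
    ),
    chiBonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                    c("CD", "CE")),
    coordAtom = "NZ",
    reach = 6.4
  ),

  ## glutamate (net -1): salt-bridge acceptor via OE2
  GLU = list(
    charge = -1,
    atoms = rbind(
      .tplAtom("CB", "C", 0.0, "N", "C", "CA", 1.530, 110.6, 122.6),
      .tplAtom("CG", "C", 0.0, "N", "CA", "CB", 1.520, 114.1, -60.0),
      .tplAtom("CD", "C", 0.0, "CA", "CB", "CG", 1.520, 112.6, 180.0),
      .tplAtom("OE1", "O", -0.5, "CB", "CG", "CD", 1.250, 118.3, 0.0),
      .tplAtom("OE2", "O", -0.5, "CB", "CG", "CD", 1.250, 118.3, 180.0)
    ),
    bonds = rbind(
      .tplBond("CA", "CB", 250, 1.530),
      .tplBond("CB", "CG", 250, 1.520),
      .tplBond("CG", "CD", 250, 1.520),
      .tplBond("CD", "OE1", 400, 1.250),
      .tplBond("CD", "OE2", 400, 1.250)
    ),
    angles = rbind(
      .tplAngle("N", "CA", "CB", 50, 110.5),
      .tplAngle("CA", "CB", "CG", 50, 114.1),
      .tplAngle("CB", "CG", "CD", 50, 112.6),
      .tplAngle("CG", "CD", "OE1", 60, 118.3),
      .tplAngle("CG", "CD", "OE2", 60, 118.3),
      .tplAngle("OE1", "CD", "OE2", 60, 123.4)
    ),
    dihedrals = rbind(
      .tplDihedral("N", "CA", "CB", "CG", 0.3, 3L, 0),
      .tplDihedral("CA", "CB", "CG", "CD", 0.3, 3L, 0)
    ),
    chiBonds = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD")),
    coordAtom = "OE2",
    reach = 5.0
  ),

  ## minimal tryptophan stub (mutation bookkeeping only; no restraint
  ## term references it)
  TRP = list(
    charge = 0,
    atoms = rbind(
      .tplAtom("CB", "C", 0.0, "N", "C", "CA", 1.530, 110.6, 122.6),
      .tplAtom("CG", "C", 0.0, "N", "CA", "CB", 1.500, 113.6, -60.0),
      .tplAtom("CD1", "C", 0.0, "CA", "CB", "CG", 1.365, 126.9, 90.0),
      .tplAtom("CD2", "C", 0.0, "CA", "CB", "CG", 1.433, 126.6, -90.0)
    ),
    bonds = rbind(
      .tplBond("CA", "CB", 250, 1.530),
      .tplBond("CB", "CG", 250, 1.500),
      .tplBond("CG", "CD1", 350, 1.365),
      .tplBond("CG", "CD2", 350, 1.433)
    ),
    angles = rbind(
      .tplAngle("N", "CA", "CB", 50, 110.5),
      .tplAngle("CA", "CB", "CG", 50, 113.6),
      .tplAngle("CB", "CG", "CD1", 50, 126.9),
      .tplAngle("CB", "CG", "CD2", 50, 126.6)
    ),
    dihedrals = .tplDihedral("N", "CA", "CB", "CG", 0.3, 3L, 0),
    chiBonds = list(c("CA", "CB"), c("CB", "CG")),
    coordAtom = "CG",
    reach = 4.0
  ),

  ## simplified MTSSL spin-label side chain grafted on a cysteine:
  ## CB-SG-SD disulfide linker, then a short arm carrying the nitroxide
  ## N-O; the nitroxide oxygen ON is the distance probe
  MTSSL = list(
    charge = 0,
    atoms = rbind(
      .tplAtom("CB", "C", 0.0, "N", "C", "CA", 1.530, 110.6, 122.6),
      .tplAtom("SG", "S", 0.0, "N", "CA", "CB", 1.820, 114.4, -60.0),
      .tplAtom("SD", "S", 0.0, "CA", "CB", "SG", 2.030, 103.8, 180.0),
      .tplAtom("CE", "C", 0.0, "CB", "SG", "SD", 1.810, 103.8, -90.0),
      .tplAtom("C3", "C", 0.0, "SG", "SD", "CE", 1.510, 112.0, 180.0),
      .tplAtom("NN", "N", 0.0, "SD", "CE", "C3", 1.450, 115.0, 180.0),
      .tplAtom("ON", "O", 0.0, "CE", "C3", "NN", 1.280, 125.0, 180.0)
    ),
    bonds = rbind(
      .tplBond("CA", "CB", 250, 1.530),
      .tplBond("CB", "SG", 200, 1.820),
      .tplBond("SG", "SD", 180, 2.030),
      .tplBond("SD", "CE", 200, 1.810),
      .tplBond("CE", "C3", 250, 1.510),
      .tplBond("C3", "NN", 300, 1.450),
      .tplBond("NN", "ON", 400, 1.280)
    ),
    angles = rbind(
      .tplAngle("N", "CA", "CB", 50, 110.5),
      .tplAngle("CA", "CB", "SG", 50, 114.4),
      .tplAngle("CB", "SG", "SD", 50, 103.8),
      .tplAngle("SG", "SD", "CE", 50, 103.8),
      .tplAngle("SD", "CE", "C3", 50, 112.0),
      .tplAngle("CE", "C3", "NN", 50, 115.0),
      .tplAngle("C3", "NN", "ON", 60, 125.0)
    ),
    dihedrals = rbind(
      .tplDihedral("N", "CA", "CB", "SG", 0.3, 3L, 0),
      .tplDihedral("CA", "CB", "SG", "SD", 0.3, 3L, 0),
      .tplDihedral("CB", "SG", "SD", "CE", 0.3, 3L, 0),
      .tplDihedral("SG", "SD", "CE", "C3", 0.3, 3L, 0),
      .tplDihedral("SD", "CE", "C3", "NN", 0.3, 3L, 0)
    ),
    chiBonds = list(c("CA", "CB"), c("CB", "SG"), c("SG", "SD"),
                    c("SD", "CE"), c("CE", "C3")),
    coordAtom = "ON",
    probeAtom = "ON",
    reach = 8.0
  ),

  ## dummy spin-label: a single pseudo-atom on a fixed-length tether
  ## from CA standing in for the full nitroxide arm
  DUM = list(
    charge = 0,
    atoms = .tplAtom("DU", "X", 0.0, "N", "C", "CA", 6.20, 110.0, -60.0),
    bonds = .tplBond("CA", "DU", 10, 6.20),
    angles = .tplAngle("N", "CA", "DU", 2, 110.0),
    dihedrals = NULL,
    chiBonds = list(c("N", "CA"), c("C", "CA")),
    coordAtom = "DU",
    probeAtom = "DU",
    reach = 6.2
  )
)

.ionSpecs <- list(
  cd_bridge = list(ion = "CD", resname = "CD", charge = 2),
  mg_bridge = list(ion = "MG", resname = "MG", charge = 2),
  zn_bridge = list(ion = "ZN", resname = "ZN", charge = 2)
)

.bridgeResidues <- c(cd_bridge = "CYS", mg_bridge = "ASP",
                     zn_bridge = "HIS")
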