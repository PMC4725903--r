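{
  "_schema": "msclattice-defaults-1",
  "_comment": "Versioned model parameters for MscL continuum-elastic calculations. All lengths in nm, energies in kBT at room temperature, tensions in kBT/nm^2, angles in radians unless suffixed _deg. Entries carry a _source tag describing the provenance class of the value.",
  "bilayer": {
    "kappa_b": 20.0,
    "K_t": 60.0,
    "a": 1.6,
    "tau": 0.0,
    "_source": "effective elastic constants for E. coli-like lipid bilayers from micropipette/stress-strain experiments; a is one-half the unperturbed hydrophobic thickness"
  },
  "pentamer": {
    "closed": { "R": 2.27, "eps": 0.22 },
    "open":   { "R": 3.49, "eps": 0.11 },
    "symmetry_order": 5,
    "_source": "five-fold clover-leaf fits to the M. tuberculosis closed structure (PDB 2OAR) and proposed open-state models"
  },
  "tetramer": {
    "closed": { "eps": 0.22 },
    "open":   { "eps": 0.11 },
    "symmetry_order": 4,
    "R_policy": "matched-area",
    "_source": "tetragonal-contour undulation amplitudes are not fixed directly by the S. aureus structure (PDB 3HZQ); values adopted from the anisotropic shape-modelling literature, with R chosen so tetramer and pentamer cross-sectional areas agree state by state"
  },
  "hydrophobic_thickness": {
    "closed": 3.8,
    "open": 2.5,
    "_source": "structural estimates of the MscL hydrophobic belt in the closed and open states; boundary mismatch U = thickness/2 - a"
  },
  "steric": {
    "edge_clearance": 1.0,
    "d_cut": 13.0,
    "_source": "clearance approximates one lipid diameter between protein edges; d_cut is where tabulated |E_int| falls below 0.05 kBT at default bilayer parameters"
  },
  "tabulation": {
    "dd": 0.1,
    "dw_deg": 2.0,
    "_source": "study-grade translational and orientational grid resolutions"
  },
  "mesh": {
    "h_near_fraction": 200,
    "h_far_factor": 4.0,
    "margin_lambda": 10.0,
    "_source": "h_near = contour perimeter / h_near_fraction; domain margin in units of the elastic decay length lambda = (kappa_b a^2 / K_t)^(1/4)"
  },
  "mc": {
    "unit_displacement": 0.1,
    "unit_rotation": 0.05,
    "T_start": 1.5,
    "T_end": 0.01,
    "n_steps": 1000000,
    "_source": "trial-move amplitudes give roughly half of moves accepted near room temperature; linear cooling in units of room temperature"
  },
  "gating": {
    "tau_grid": [0.5, 1.0, 1.5, 2.0],
    "_source": "membrane-tension range for activation-barrier scans, spanning sub-gating to near-gating tensions"
  }
}
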