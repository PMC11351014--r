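-- chemregistry relational schema, version 1.
-- String equality on the hash columns is the only search primitive, so
-- every layer column and both combined-hash columns are indexed.

CREATE TABLE registry_config (
    id INTEGER PRIMARY KEY CHECK (id = 1),
    config TEXT NOT NULL
);

CREATE TABLE molecules (
    molregno INTEGER PRIMARY KEY AUTOINCREMENT,
    formula TEXT NOT NULL,
    canonical_smiles TEXT NOT NULL,
    tautomer_hash TEXT NOT NULL,
    no_stereo_smiles TEXT NOT NULL,
    no_stereo_tautomer_hash TEXT NOT NULL,
    sgroup_data TEXT NOT NULL,
    escape_layer TEXT NOT NULL,
    full_hash TEXT NOT NULL UNIQUE,
    standardized_molblock TEXT,
    standardization_applied TEXT,
    registered_at TEXT NOT NULL
);

CREATE INDEX idx_molecules_formula ON molecules(formula);
CREATE INDEX idx_molecules_canonical_smiles ON molecules(canonical_smiles);
CREATE INDEX idx_molecules_tautomer_hash ON molecules(tautomer_hash);
CREATE INDEX idx_molecules_no_stereo_smiles ON molecules(no_stereo_smiles);
CREATE INDEX idx_molecules_no_stereo_tautomer_hash
    ON molecules(no_stereo_tautomer_hash);
CREATE INDEX idx_molecules_sgroup_data ON molecules(sgroup_data);
CREATE INDEX idx_molecules_escape ON molecules(escape_layer);

CREATE TABLE raw_inputs (
    molregno INTEGER PRIMARY KEY REFERENCES molecules(molregno),
    raw TEXT NOT NULL,
    format TEXT NOT NULL
);

CREATE TABLE conformers (
    molregno INTEGER NOT NULL REFERENCES molecules(molregno),
    conf_id INTEGER NOT NULL,
    conf_hash TEXT NOT NULL,
    coords TEXT NOT NULL,
    molblock TEXT,
    registered_at TEXT NOT NULL,
    PRIMARY KEY (molregno, conf_id),
    UNIQUE (molregno, conf_hash)
);

CREATE INDEX idx_conformers_hash ON conformers(conf_hash);

CREATE TABLE experiment_types (
    name TEXT PRIMARY KEY,
    definition TEXT NOT NULL
);

-- global index of experiments across all types; resolves an experiment
-- UUID to its per-type metadata/data tables
CREATE TABLE experiments (
    experiment_id TEXT PRIMARY KEY,
    type_name TEXT NOT NULL REFERENCES experiment_types(name)
);
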