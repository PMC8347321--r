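"""Batch chemistry backend for the cypsubstrate R package.

Reads a JSON task description, performs RDKit structure handling, writes a
JSON result. One process invocation handles a whole batch of molecules so the
interpreter startup cost is paid once per call, not per molecule.

Tasks:
  standardize   -- parse + ChEMBL-style standardization (+ optional tautomer
                   canonicalization), reporting status/reason per record
  featurize     -- MACCS keys, Morgan fingerprints, RDKit 2D descriptors,
                   Morgan radius-0/1 substructure identifiers (for embeddings)
  parse_sdf     -- read an SDF file into (id, smiles, properties) records
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, GraphDescriptors, MACCSkeys
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

_TAUTOMER_ENUMERATOR = None


def tautomer_enumerator():
    global _TAUTOMER_ENUMERATOR
    if _TAUTOMER_ENUMERATOR is None:
        _TAUTOMER_ENUMERATOR = rdMolStandardize.TautomerEnumerator()
    return _TAUTOMER_ENUMERATOR


def standardize_one(smiles, canonical_tautomer=True):
    """ChEMBL-rule standardization of a single structure.

    Cleanup (normalization of drawing variants, kekulization, neutralization
    of simple cases), parent extraction (salt/solvent stripping, duplicate
    fragment removal), isotope removal, neutralization, optional tautomer
    canonicalization, stereo removal.
    """
    if smiles is None or str(smiles).strip() == "":
        return {"status": "missing_structure", "smiles": None}
    mol = Chem.MolFromSmiles(str(smiles))
    if mol is None:
        return {"status": "parse_error", "smiles": None}
    try:
        mol = rdMolStandardize.Cleanup(mol)
        mol = rdMolStandardize.IsotopeParent(mol, skipStandardize=True)
        mol = rdMolStandardize.ChargeParent(mol, skipStandardize=True)
        if mol is None or mol.GetNumAtoms() == 0:
            return {"status": "standardization_error", "smiles": None}
        if canonical_tautomer:
            mol = tautomer_enumerator().Canonicalize(mol)
        Chem.RemoveStereochemistry(mol)
        out = Chem.MolToSmiles(mol)
        elements = sorted({a.GetSymbol() for a in mol.GetAtoms()})
        return {
            "status": "ok",
            "smiles": out,
            "elements": elements,
            "n_atoms": mol.GetNumAtoms(),
            "n_aromatic_atoms": sum(a.GetIsAromatic() for a in mol.GetAtoms()),
            "n_fragments": len(Chem.GetMolFrags(mol)),
        }
    except Exception:
        return {"status": "standardization_error", "smiles": None}


def run_standardize(payload):
    taut = bool(payload.get("canonical_tautomer", True))
    return [standardize_one(s, taut) for s in payload["smiles"]]


def physchem_one(mol):
    """All RDKit 2D descriptors; Ipc uses the averaged-information-content
    variant (avg=1) so values stay within float range."""
    vals = Descriptors.CalcMolDescriptors(mol)
    vals["Ipc"] = GraphDescriptors.Ipc(mol, avg=1)
    out = {}
    for k, v in vals.items():
        try:
            v = float(v)
        except (TypeError, ValueError):
            return None
        if not math.isfinite(v):
            return None
        out[k] = v
    return out


def run_featurize(payload):
    features = payload["features"]
    results = []
    for smi in payload["smiles"]:
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            results.append({"status": "parse_error"})
            continue
        rec = {"status": "ok"}
        if "maccs" in features:
            fp = MACCSkeys.GenMACCSKeys(mol)
            # bit 0 of the 167-bit RDKit vector is unused; keys are 1..166
            rec["maccs_on"] = [b for b in fp.GetOnBits() if b >= 1]
        if "morgan2" in features:
            bv = AllChem.GetMorganFingerprintAsBitVect(
                mol,
                int(payload.get("radius", 2)),
                nBits=int(payload.get("n_bits", 2048)),
            )
            rec["morgan_on"] = list(bv.GetOnBits())
        if "physchem2d" in features:
            vals = physchem_one(mol)
            if vals is None:
                rec["status"] = "descriptor_error"
            else:
                rec["physchem"] = vals
        if "morgan_ids" in features:
            # unhashed Morgan identifiers with multiplicity, radius 0 and 1,
            # the substructure "words" of a mol2vec-style embedding
            fpu = AllChem.GetMorganFingerprint(mol, 1)
            nz = fpu.GetNonzeroElements()
            rec["morgan_ids"] = {str(k): int(v) for k, v in nz.items()}
        results.append(rec)
    return results


def run_parse_sdf(payload):
    supplier = Chem.SDMolSupplier(payload["path"], sanitize=True)
    records = []
    for i, mol in enumerate(supplier):
        if mol is None:
            records.append({"status": "parse_error", "index": i})
            continue
        props = {k: mol.GetProp(k) for k in mol.GetPropNames()}
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        records.append(
            {
                "status": "ok",
                "index": i,
                "name": name,
                "smiles": Chem.MolToSmiles(mol),
                "properties": props,
            }
        )
    return records


TASKS = {
    "standardize": run_standardize,
    "featurize": run_featurize,
    "parse_sdf": run_parse_sdf,
}


def main(argv):
    in_path, out_path = argv[1], argv[2]
    with open(in_path) as fh:
        payload = json.load(fh)
    task = payload["task"]
    result = TASKS[task](payload)
    with open(out_path, "w") as fh:
        json.dump({"task": task, "results": result}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
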