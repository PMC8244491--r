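#!/usr/bin/env python
"""Batch molecular-perception sidecar backed by RDKit.

Called by the R package through system2(); one process per batch of
molecules, JSON out.  Commands:

  featurize --in FILE --format smiles|sdf --out FILE.json
            [--embed3d] [--seed N] [--n-confs N]
  embed-sdf --in FILE.smi --out FILE.sdf --seed N

Per heavy atom a seven-channel property vector is produced:
  donor, acceptor, sp2, lipophilicity, size, electronegativity, charge
Hydrogens are merged onto their heavy atom (H counts, Gasteiger charge and
Crippen logP contributions).  Rules are Lipinski-style (donor: N/O with >=1
H; acceptor: any N/O), sp2 from RDKit hybridisation perception, lipophilicity
from Crippen atomic contributions, size = (rvdw/rvdw_C)^3, electronegativity
= Pauling EN minus carbon's 2.55, charge = Gasteiger partial charge.
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, MACCSkeys, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

PAULING_EN = {
    1: 2.20, 5: 2.04, 6: 2.55, 7: 3.04, 8: 3.44, 9: 3.98,
    15: 2.19, 16: 2.58, 17: 3.16, 35: 2.96, 53: 2.66,
}
EN_C = 2.55
PT = Chem.GetPeriodicTable()
RVDW_C = PT.GetRvdw(6)

FP_SCHEME = "MACCS"
FP_NBITS = 167


def _read_input(path, fmt):
    """Yield (id, mol_without_Hs, had_3d) tuples; invalid entries as (id, None, False)."""
    out = []
    if fmt == "smiles":
        with open(path) as fh:
            for i, line in enumerate(fh):
                line = line.strip()
                if not line or line.startswith("#"):
                    continue
                parts = line.split(None, 1)
                smi = parts[0]
                lid = parts[1].strip() if len(parts) > 1 else "mol%d" % (i + 1)
                mol = Chem.MolFromSmiles(smi)
                out.append((lid, mol, False))
    elif fmt == "sdf":
        supp = Chem.SDMolSupplier(path, removeHs=False)
        for i, mol in enumerate(supp):
            if mol is None:
                out.append(("sdf_entry%d" % (i + 1), None, False))
                continue
            lid = mol.GetProp("_Name").strip() if mol.HasProp("_Name") else ""
            if not lid:
                lid = "mol%d" % (i + 1)
            out.append((lid, mol, mol.GetNumConformers() > 0))
    else:
        raise ValueError("unknown format: %s" % fmt)
    return out


def _atom_properties(molh):
    """Seven-channel vectors for heavy atoms of molh (explicit Hs present)."""
    AllChem.ComputeGasteigerCharges(molh)
    crippen = rdMolDescriptors._CalcCrippenContribs(molh)
    conf = molh.GetConformer() if molh.GetNumConformers() else None
    atoms = []
    for atom in molh.GetAtoms():
        if atom.GetAtomicNum() == 1:
            continue
        idx = atom.GetIdx()
        z = atom.GetAtomicNum()
        nh = sum(1 for nb in atom.GetNeighbors() if nb.GetAtomicNum() == 1)
        charge = float(atom.GetProp("_GasteigerCharge"))
        logp = crippen[idx][0]
        for nb in atom.GetNeighbors():
            if nb.GetAtomicNum() == 1:
                charge += float(nb.GetProp("_GasteigerCharge"))
                logp += crippen[nb.GetIdx()][0]
        rec = {
            "element": atom.GetSymbol(),
            "donor": 1 if (z in (7, 8) and nh >= 1) else 0,
            "acceptor": 1 if z in (7, 8) else 0,
            "sp2": 1 if atom.GetHybridization() == Chem.HybridizationType.SP2 else 0,
            "lipophilicity": round(logp, 6),
            "size": round((PT.GetRvdw(z) / RVDW_C) ** 3, 6),
            "electronegativity": round(PAULING_EN.get(z, EN_C) - EN_C, 6),
            "charge": round(charge, 6),
        }
        if conf is not None:
            pos = conf.GetAtomPosition(idx)
            rec["x"], rec["y"], rec["z"] = round(pos.x, 4), round(pos.y, 4), round(pos.z, 4)
        atoms.append(rec)
    return atoms


def _embed(molh, seed):
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    ok = AllChem.EmbedMolecule(molh, params)
    if ok != 0:  # fall back to random-coordinate DG, still seeded
        params.useRandomCoords = True
        ok = AllChem.EmbedMolecule(molh, params)
    if ok != 0:
        return False
    AllChem.MMFFOptimizeMolecule(molh, maxIters=500)
    return True


def cmd_featurize(args):
    entries = _read_input(args.infile, args.format)
    mols, n_invalid = [], 0
    for k, (lid, mol, had3d) in enumerate(entries):
        if mol is None:
            n_invalid += 1
            mols.append({"id": lid, "valid": False, "error": "unparseable entry"})
            continue
        try:
            mol_noh = Chem.RemoveHs(mol)
            can = Chem.MolToSmiles(mol_noh)
            fp = MACCSkeys.GenMACCSKeys(mol_noh)
            molh = Chem.AddHs(mol, addCoords=had3d)
            if args.embed3d and not had3d:
                if not _embed(molh, args.seed + 7919 * k):
                    n_invalid += 1
                    mols.append({"id": lid, "valid": False,
                                 "error": "3D embedding failed"})
                    continue
                had3d = True
            atoms = _atom_properties(molh)
            mols.append({
                "id": lid,
                "valid": True,
                "smiles": can,
                "has_conformer": bool(had3d),
                "fingerprint": {"scheme": FP_SCHEME, "nbits": FP_NBITS,
                                "bits": sorted(int(b) for b in fp.GetOnBits())},
                "atoms": atoms,
            })
        except Exception as exc:  # sanitisation/valence failures
            n_invalid += 1
            mols.append({"id": lid, "valid": False, "error": str(exc)})
    payload = {
        "backend": "rdkit",
        "rdkit_version": Chem.rdBase.rdkitVersion,
        "fingerprint_scheme": FP_SCHEME,
        "fingerprint_nbits": FP_NBITS,
        "n_invalid": n_invalid,
        "molecules": mols,
    }
    with open(args.out, "w") as fh:
        json.dump(payload, fh)


def cmd_embed_sdf(args):
    entries = _read_input(args.infile, "smiles")
    writer = Chem.SDWriter(args.out)
    writer.SetKekulize(True)
    n_fail = 0
    for k, (lid, mol, _) in enumerate(entries):
        if mol is None:
            n_fail += 1
            continue
        molh = Chem.AddHs(mol)
        if not _embed(molh, args.seed + 7919 * k):
            n_fail += 1
            continue
        molh.SetProp("_Name", lid)
        molh.SetProp("embedder", "RDKit ETKDGv3 %s seed=%d"
                     % (Chem.rdBase.rdkitVersion, args.seed + 7919 * k))
        writer.write(molh)
    writer.close()
    sys.stderr.write("embed-sdf: %d written, %d failed\n"
                     % (len(entries) - n_fail, n_fail))


def main():
    ap = argparse.ArgumentParser(description=__doc__)
    sub = ap.add_subparsers(dest="cmd", required=True)
    f = sub.add_parser("featurize")
    f.add_argument("--in", dest="infile", required=True)
    f.add_argument("--format", choices=["smiles", "sdf"], required=True)
    f.add_argument("--out", required=True)
    f.add_argument("--embed3d", action="store_true")
    f.add_argument("--seed", type=int, default=0)
    f.set_defaults(func=cmd_featurize)
    e = sub.add_parser("embed-sdf")
    e.add_argument("--in", dest="infile", required=True)
    e.add_argument("--out", required=True)
    e.add_argument("--seed", type=int, default=0)
    e.set_defaults(func=cmd_embed_sdf)
    args = ap.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
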