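"""Batch chemistry backend for the ionstate R package.

Reads one JSON request from the file given as argv[1] and writes a JSON
response to argv[2].  All molecule-level primitives (SMILES parsing,
standardization, SMARTS matching with atom indices, formal-charge edits,
canonicalization) live here, on top of RDKit.  All protonation *decisions*
are made by the R code; this process never sees a pH.

Request format:
  {"op": "match",  "smiles": [...], "patterns": [{"name":..., "smarts":...}]}
  {"op": "edit",   "jobs": [{"smiles":..., "edits":[{"atom":i, "charge":c,
                                                     "h": int|null}]}]}
  {"op": "parse",  "smiles": [...]}

Atom indices exchanged with R are 0-based and refer to the atom order of the
*returned* standardized SMILES (the string re-parses into that same order).
"""

import json
import sys

from rdkit import Chem
from rdkit import RDLogger
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

_NORMALIZER = rdMolStandardize.Normalizer()


def _fix_azides(mol):
    """Rewrite any N~N~N chain to the charge-separated azide form.

    Accepts unsanitized molecules, so hypervalent neutral spellings such as
    N=N=N and NN#N are repaired before valence checking.  The written form is
    R-N=[N+]=[N-] (R may be H).
    """
    rw = Chem.RWMol(mol)
    hits = []
    for atom in rw.GetAtoms():
        if atom.GetAtomicNum() != 7 or atom.GetDegree() != 2:
            continue
        nbrs = [a for a in atom.GetNeighbors() if a.GetAtomicNum() == 7]
        if len(nbrs) != 2:
            continue
        term = [a for a in nbrs if a.GetDegree() == 1]
        if not term:
            continue
        # n3: a terminal nitrogen; n1: the other end (may carry R or H)
        n3 = max(term, key=lambda a: a.GetIdx())
        n1 = nbrs[0] if nbrs[1].GetIdx() == n3.GetIdx() else nbrs[1]
        hits.append((n1.GetIdx(), atom.GetIdx(), n3.GetIdx()))
    for i1, i2, i3 in hits:
        n1, n2, n3 = (rw.GetAtomWithIdx(i) for i in (i1, i2, i3))
        rw.GetBondBetweenAtoms(i1, i2).SetBondType(Chem.BondType.DOUBLE)
        rw.GetBondBetweenAtoms(i2, i3).SetBondType(Chem.BondType.DOUBLE)
        n1.SetFormalCharge(0)
        n2.SetFormalCharge(1)
        n3.SetFormalCharge(-1)
        for a, h in ((n1, 1 if n1.GetDegree() == 1 else 0), (n2, 0), (n3, 0)):
            a.SetNoImplicit(True)
            a.SetNumExplicitHs(h)
    return rw.GetMol()


def _largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return mol, False
    best = max(frags, key=lambda f: (f.GetNumHeavyAtoms(), Chem.MolToSmiles(f)))
    return best, True


def standardize(smiles):
    """Parse + standardize one SMILES.  Returns (mol, dropped_fragment) or
    raises ValueError."""
    mol = Chem.MolFromSmiles(smiles, sanitize=False)
    if mol is None:
        raise ValueError("unparseable SMILES: %r" % smiles)
    mol = _fix_azides(mol)
    mol = _NORMALIZER.normalize(mol)
    Chem.SanitizeMol(mol)
    mol, dropped = _largest_fragment(mol)
    if dropped:
        Chem.SanitizeMol(mol)
    return mol, dropped


def _canonical_with_order(mol):
    """Canonical SMILES plus the map original-index -> output-order index."""
    smi = Chem.MolToSmiles(mol)
    order = json.loads(mol.GetProp("_smilesAtomOutputOrder"))
    remap = {orig: pos for pos, orig in enumerate(order)}
    return smi, remap


def op_match(req):
    pats = []
    for p in req.get("patterns", []):
        q = Chem.MolFromSmarts(p["smarts"])
        if q is None:
            return {"error": "invalid SMARTS for rule %r: %r"
                    % (p["name"], p["smarts"])}
        pats.append((p["name"], q))
    out = []
    for smi in req["smiles"]:
        try:
            mol, dropped = standardize(smi)
        except Exception as exc:  # noqa: BLE001 - reported to R per record
            out.append({"ok": False, "error": str(exc)})
            continue
        can, remap = _canonical_with_order(mol)
        matches = {}
        for name, q in pats:
            raw = mol.GetSubstructMatches(q, uniquify=True)
            if raw:
                matches[name] = [[remap[i] for i in m] for m in raw]
        out.append({"ok": True, "smiles": can,
                    "fragment_dropped": dropped,
                    "n_heavy": mol.GetNumHeavyAtoms(),
                    "matches": matches})
    return {"results": out}


def _apply_edit(mol, atom_idx, charge, h):
    atom = mol.GetAtomWithIdx(atom_idx)
    atom.SetFormalCharge(int(charge))
    if h is None:
        # let valence rules refill implicit hydrogens
        atom.SetNoImplicit(False)
        atom.SetNumExplicitHs(0)
    else:
        atom.SetNoImplicit(True)
        atom.SetNumExplicitHs(int(h))


def op_edit(req):
    out = []
    for job in req["jobs"]:
        try:
            mol = Chem.MolFromSmiles(job["smiles"], sanitize=True)
            if mol is None:
                raise ValueError("unparseable SMILES: %r" % job["smiles"])
            rw = Chem.RWMol(mol)
            for e in job["edits"]:
                _apply_edit(rw, e["atom"], e["charge"], e.get("h"))
            m2 = rw.GetMol()
            Chem.SanitizeMol(m2)
            out.append({"ok": True, "smiles": Chem.MolToSmiles(m2)})
        except Exception as exc:  # noqa: BLE001
            out.append({"ok": False, "error": str(exc)})
    return {"results": out}


def op_parse(req):
    out = []
    for smi in req["smiles"]:
        try:
            mol, dropped = standardize(smi)
            can, _ = _canonical_with_order(mol)
            out.append({"ok": True, "smiles": can,
                        "fragment_dropped": dropped,
                        "n_heavy": mol.GetNumHeavyAtoms()})
        except Exception as exc:  # noqa: BLE001
            out.append({"ok": False, "error": str(exc)})
    return {"results": out}


OPS = {"match": op_match, "edit": op_edit, "parse": op_parse}


def main(argv):
    with open(argv[1]) as fh:
        req = json.load(fh)
    op = OPS.get(req.get("op"))
    resp = {"error": "unknown op %r" % req.get("op")} if op is None else op(req)
    with open(argv[2], "w") as fh:
        json.dump(resp, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
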