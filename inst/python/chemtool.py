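"""Batched RDKit helper for the screenclean R package.

Reads one JSON request object on stdin:
    {"op": <name>, "smiles": [...], ...op-specific args}
and writes a JSON array with one result object per input SMILES on stdout.
Invalid SMILES yield {"ok": false}; the caller decides how to surface that.
Non-finite numbers are emitted as null (strict JSON).
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold
from rdkit.Chem import rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

_FRAGMENT_CHOOSER = rdMolStandardize.LargestFragmentChooser()
_UNCHARGER = rdMolStandardize.Uncharger()


def _finite(x):
    try:
        x = float(x)
    except (TypeError, ValueError):
        return None
    return x if math.isfinite(x) else None


def op_standardize(smiles, req):
    """MolVS-style cleanup -> largest organic fragment -> uncharge -> canonical.

    stereo_mode == "collapse" strips stereo descriptors before writing.
    Returns the canonical parent SMILES and its average molecular weight.
    """
    collapse = req.get("stereo_mode", "as_given") == "collapse"
    out = []
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False})
            continue
        try:
            mol = rdMolStandardize.Cleanup(mol)
            mol = _FRAGMENT_CHOOSER.choose(mol)
            mol = _UNCHARGER.uncharge(mol)
            if collapse:
                Chem.RemoveStereochemistry(mol)
            out.append({
                "ok": True,
                "std": Chem.MolToSmiles(mol),
                "mw": _finite(Descriptors.MolWt(mol)),
                "n_frags": len(Chem.GetMolFrags(mol)),
            })
        except Exception:
            out.append({"ok": False})
    return out


def op_mw(smiles, req):
    out = []
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False})
        else:
            out.append({"ok": True, "mw": _finite(Descriptors.MolWt(mol))})
    return out


def op_scaffold(smiles, req):
    """Bemis-Murcko framework; acyclic molecules map to the empty string.

    Stereo is stripped first so enantiomers share one scaffold.
    """
    out = []
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False})
            continue
        try:
            Chem.RemoveStereochemistry(mol)
            scaf = MurckoScaffold.GetScaffoldForMol(mol)
            out.append({"ok": True, "scaffold": Chem.MolToSmiles(scaf)})
        except Exception:
            out.append({"ok": False})
    return out


def op_descriptor_names(smiles, req):
    return [{"ok": True, "names": sorted(n for n, _ in Descriptors._descList)}]


def op_descriptors(smiles, req):
    names = req["names"]
    table = dict(Descriptors._descList)
    funcs = [(n, table[n]) for n in names]
    out = []
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False})
            continue
        vals = []
        for _, fn in funcs:
            try:
                vals.append(_finite(fn(mol)))
            except Exception:
                vals.append(None)
        out.append({"ok": True, "values": vals})
    return out


_SMARTS = {
    # amide N-C(=O) with carbon on both sides: peptide-backbone-like bond
    "backbone_amide": Chem.MolFromSmarts("[#6][NX3][CX3](=O)[#6]"),
    "carboxylic_acid": Chem.MolFromSmarts("[CX3](=O)[OX2H1,OX1-]"),
    "phosphate": Chem.MolFromSmarts("[PX4](=[OX1])"),
    # ring carbon bonded to a ring oxygen and exocyclically to nitrogen
    "glycosidic": Chem.MolFromSmarts("[CX4;R](-[OX2;R])-[#7]"),
}
_HALOGENS = {9, 17, 35, 53}


def _longest_aliphatic_chain(mol):
    """Longest simple path through acyclic sp3 carbons (tree components)."""
    eligible = set()
    for atom in mol.GetAtoms():
        if (atom.GetAtomicNum() == 6 and not atom.GetIsAromatic()
                and not atom.IsInRing()
                and atom.GetHybridization() == Chem.HybridizationType.SP3):
            eligible.add(atom.GetIdx())
    if not eligible:
        return 0
    adj = {i: [] for i in eligible}
    for bond in mol.GetBonds():
        a, b = bond.GetBeginAtomIdx(), bond.GetEndAtomIdx()
        if a in eligible and b in eligible:
            adj[a].append(b)
            adj[b].append(a)

    def far(start):
        seen = {start}
        frontier = [(start, 1)]
        best = (start, 1)
        while frontier:
            node, d = frontier.pop()
            if d > best[1]:
                best = (node, d)
            for nxt in adj[node]:
                if nxt not in seen:
                    seen.add(nxt)
                    frontier.append((nxt, d + 1))
        return best

    longest = 0
    visited = set()
    for i in eligible:
        if i in visited:
            continue
        comp = {i}
        stack = [i]
        while stack:
            n = stack.pop()
            for nxt in adj[n]:
                if nxt not in comp:
                    comp.add(nxt)
                    stack.append(nxt)
        visited |= comp
        # double sweep: farthest node from an arbitrary node, then again
        end, _ = far(i)
        _, depth = far(end)
        longest = max(longest, depth)
    return longest


def op_features(smiles, req):
    out = []
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False})
            continue
        out.append({
            "ok": True,
            "n_halogen": sum(1 for a in mol.GetAtoms()
                             if a.GetAtomicNum() in _HALOGENS),
            "n_aromatic_rings": rdMolDescriptors.CalcNumAromaticRings(mol),
            "n_rotatable_bonds": rdMolDescriptors.CalcNumRotatableBonds(mol),
            "n_backbone_amide": len(mol.GetSubstructMatches(
                _SMARTS["backbone_amide"])),
            "has_carboxylic_acid": mol.HasSubstructMatch(
                _SMARTS["carboxylic_acid"]),
            "has_phosphate": mol.HasSubstructMatch(_SMARTS["phosphate"]),
            "has_glycosidic": mol.HasSubstructMatch(_SMARTS["glycosidic"]),
            "longest_aliphatic_chain": _longest_aliphatic_chain(mol),
        })
    return out


OPS = {
    "standardize": op_standardize,
    "mw": op_mw,
    "scaffold": op_scaffold,
    "descriptor_names": op_descriptor_names,
    "descriptors": op_descriptors,
    "features": op_features,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        sys.stderr.write("chemtool: unknown op %r\n" % op)
        sys.exit(2)
    result = OPS[op](req.get("smiles", []), req)
    json.dump(result, sys.stdout, allow_nan=False)
    sys.stdout.write("\n")


if __name__ == "__main__":
    main()
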