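#!/usr/bin/env python
"""Batched JSON bridge exposing RDKit (and sklearn t-SNE) primitives to R.

Usage: python rdkit_bridge.py <request.json> <response.json>

The request is a JSON object {"op": <name>, ...payload}; the response is
{"ok": true, "result": ...} or {"ok": false, "error": "..."}.  Every op is
vectorised over lists of SMILES so one process start-up serves a whole batch.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, rdFingerprintGenerator, rdMolDescriptors
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def _largest_fragment(mol):
    """Largest organic fragment: most heavy atoms, ties by molecular weight."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return mol
    return max(frags, key=lambda f: (f.GetNumHeavyAtoms(), Descriptors.MolWt(f)))


def _parse(smi, strip=True):
    if smi is None or smi == "":
        return None, "empty SMILES"
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None, "unparseable SMILES"
    if strip:
        mol = _largest_fragment(mol)
        try:
            Chem.SanitizeMol(mol)
        except Exception as exc:  # pragma: no cover - rare post-split failure
            return None, f"sanitization failed: {exc}"
    return mol, None


def _nostereo_key(mol):
    m = Chem.Mol(mol)
    Chem.RemoveStereochemistry(m)
    return Chem.MolToSmiles(m)


def op_ping(req):
    import rdkit

    return {"rdkit": rdkit.__version__}


def op_canonicalize(req):
    strip = req.get("strip", True)
    out = []
    for smi in req["smiles"]:
        mol, err = _parse(smi, strip=strip)
        if mol is None:
            out.append({"ok": False, "error": err})
        else:
            out.append(
                {
                    "ok": True,
                    "canonical": Chem.MolToSmiles(mol),
                    "key": _nostereo_key(mol),
                    "n_heavy": mol.GetNumHeavyAtoms(),
                    "n_aromatic": sum(a.GetIsAromatic() for a in mol.GetAtoms()),
                }
            )
    return out


def op_properties(req):
    out = []
    for smi in req["smiles"]:
        mol, err = _parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err})
            continue
        out.append(
            {
                "ok": True,
                "mwt": Descriptors.MolWt(mol),
                "slogp": Descriptors.MolLogP(mol),
                "tpsa": Descriptors.TPSA(mol),
                "hbd": rdMolDescriptors.CalcNumHBD(mol),
                "hba": rdMolDescriptors.CalcNumHBA(mol),
                "rotb": rdMolDescriptors.CalcNumRotatableBonds(mol),
                "arom_rings": rdMolDescriptors.CalcNumAromaticRings(mol),
                "sp3_fraction": rdMolDescriptors.CalcFractionCSP3(mol),
            }
        )
    return out


def op_smarts_compile(req):
    out = []
    for sma in req["smarts"]:
        patt = Chem.MolFromSmarts(sma) if sma else None
        out.append({"ok": patt is not None})
    return out


def op_smarts_match(req):
    patts = []
    for sma in req["smarts"]:
        patt = Chem.MolFromSmarts(sma)
        if patt is None:
            raise ValueError(f"invalid SMARTS: {sma}")
        patts.append(patt)
    rows = []
    for smi in req["smiles"]:
        mol, err = _parse(smi)
        if mol is None:
            rows.append(None)
        else:
            rows.append([i for i, p in enumerate(patts) if mol.HasSubstructMatch(p)])
    return rows


def op_morgan(req):
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(req.get("radius", 2)), fpSize=int(req.get("n_bits", 1024))
    )
    out = []
    for smi in req["smiles"]:
        mol, err = _parse(smi)
        if mol is None:
            out.append(None)
        else:
            out.append(list(gen.GetFingerprint(mol).GetOnBits()))
    return out


def op_murcko(req):
    out = []
    for smi in req["smiles"]:
        mol, err = _parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err})
            continue
        scaf = MurckoScaffold.GetScaffoldForMol(mol)
        if scaf is None or scaf.GetNumAtoms() == 0:
            out.append({"ok": True, "scaffold": "", "framework": ""})
            continue
        try:
            fw = MurckoScaffold.MakeScaffoldGeneric(scaf)
            # genericization turns retained exocyclic substituents (e.g. the
            # =O of an amide linker) into methyl side chains; strip again so
            # the framework is a true topology-only fixpoint (idempotent)
            fw = MurckoScaffold.GetScaffoldForMol(fw)
            fw_smi = Chem.MolToSmiles(fw)
        except Exception:
            fw_smi = ""
        out.append({"ok": True, "scaffold": Chem.MolToSmiles(scaf), "framework": fw_smi})
    return out


def op_react(req):
    rxn = AllChem.ReactionFromSmarts(req["rxn_smarts"])
    if rxn is None:
        raise ValueError("invalid reaction SMARTS")
    out = []
    for a, b in req["pairs"]:
        ma, ea = _parse(a)
        mb, eb = _parse(b)
        if ma is None or mb is None:
            out.append({"ok": False, "error": ea or eb})
            continue
        prods = rxn.RunReactants((ma, mb))
        if not prods:
            out.append({"ok": False, "error": "reaction did not apply"})
            continue
        prod = prods[0][0]
        try:
            Chem.SanitizeMol(prod)
            out.append({"ok": True, "product": Chem.MolToSmiles(prod)})
        except Exception as exc:
            out.append({"ok": False, "error": f"product sanitization failed: {exc}"})
    return out


def op_random_smiles(req):
    """n random (non-canonical, atom-reordered) renderings per molecule."""
    out = []
    for smi in req["smiles"]:
        mol, err = _parse(smi)
        if mol is None:
            out.append(None)
        else:
            out.append(
                list(Chem.MolToRandomSmilesVect(mol, int(req.get("n", 10)), randomSeed=int(req.get("seed", 1))))
            )
    return out


def op_descriptors(req):
    n = int(req.get("n_descriptors", 200))
    desc = Descriptors._descList[:n]
    names = [d[0] for d in desc]
    rows = []
    for smi in req["smiles"]:
        mol, err = _parse(smi)
        if mol is None:
            rows.append(None)
            continue
        vals = []
        for _, fn in desc:
            try:
                v = float(fn(mol))
            except Exception:
                v = None
            vals.append(v)
        rows.append(vals)
    return {"names": names, "rows": rows}


def op_read_sdf(req):
    suppl = Chem.SDMolSupplier(req["path"], sanitize=True)
    out = []
    for i, mol in enumerate(suppl):
        if mol is None:
            out.append({"ok": False, "error": f"unparseable SDF record {i + 1}"})
        else:
            props = mol.GetPropsAsDict()
            out.append(
                {
                    "ok": True,
                    "smiles": Chem.MolToSmiles(mol),
                    "id": str(props.get("ID", mol.GetProp("_Name") if mol.HasProp("_Name") else "")),
                }
            )
    return out


def op_write_sdf(req):
    w = Chem.SDWriter(req["path"])
    n = 0
    for smi, mid in zip(req["smiles"], req["ids"]):
        mol, err = _parse(smi, strip=False)
        if mol is None:
            continue
        mol.SetProp("_Name", str(mid))
        mol.SetProp("ID", str(mid))
        w.write(mol)
        n += 1
    w.close()
    return {"written": n}


def op_tsne(req):
    import numpy as np
    from sklearn.manifold import TSNE

    x = np.asarray(req["data"], dtype=float)
    perplexity = float(req.get("perplexity", 50))
    tsne = TSNE(
        n_components=2,
        perplexity=perplexity,
        max_iter=int(req.get("iterations", 15000)),
        random_state=int(req.get("seed", 0)),
        init="pca",
    )
    coords = tsne.fit_transform(x)
    return {"coords": coords.tolist()}


OPS = {name[3:]: fn for name, fn in list(globals().items()) if name.startswith("op_")}


def main():
    req_path, resp_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    try:
        fn = OPS.get(req.get("op"))
        if fn is None:
            raise ValueError(f"unknown op: {req.get('op')}")
        result = {"ok": True, "result": fn(req)}
    except Exception as exc:
        result = {"ok": False, "error": f"{type(exc).__name__}: {exc}"}
    with open(resp_path, "w") as fh:
        json.dump(result, fh)


if __name__ == "__main__":
    main()
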