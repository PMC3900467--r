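"""Circular (Morgan/ECFP-style) substructure feature extraction backend.

Reads a TSV of ``compound_id<TAB>SMILES`` records, emits for each compound a
``FEAT<TAB>compound_id<TAB>feature...`` line whose features are canonical
rooted SMILES of every atom environment of radius 0..R (deduplicated per
compound), and ``ERROR<TAB>compound_id`` for unparseable records.

Usage: python ecfp_features.py input.tsv max_radius
"""
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def environments(mol, max_radius):
    feats = set()
    for atom in mol.GetAtoms():
        idx = atom.GetIdx()
        # radius 0: the rooted heavy-atom environment itself
        feats.add("r0:" + Chem.MolFragmentToSmiles(mol, atomsToUse=[idx],
                                                   canonical=True))
        for r in range(1, max_radius + 1):
            bonds = Chem.FindAtomEnvironmentOfRadiusN(mol, r, idx)
            if not bonds:
                continue
            amap = {}
            sub = Chem.PathToSubmol(mol, bonds, atomMap=amap)
            smi = Chem.MolToSmiles(sub, rootedAtAtom=amap[idx], canonical=True)
            if smi:
                feats.add("r%d:%s" % (r, smi))
    return feats


def main():
    path, max_radius = sys.argv[1], int(sys.argv[2])
    with open(path, encoding="utf-8") as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smi = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                print("ERROR\t%s" % cid)
                continue
            feats = sorted(environments(mol, max_radius))
            print("FEAT\t%s\t%s" % (cid, "\t".join(feats)))


if __name__ == "__main__":
    main()
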