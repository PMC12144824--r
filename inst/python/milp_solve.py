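#!/usr/bin/env python
"""Batch MILP solving via scipy.optimize.milp (bundled HiGHS).

Reads a JSON file holding a list of models and writes a JSON list of
solutions.  Model fields: nvar, obj (dense list), objconst, lb, ub,
vtype ('B'/'I'/'C' per variable), ai/aj/ax (1-based constraint triplets),
lo/hi (per-row bounds), time_limit (seconds).
"""
import json
import sys

import numpy as np
from scipy.optimize import milp, LinearConstraint, Bounds
from scipy.sparse import csc_matrix


def solve_one(m):
    n = int(m["nvar"])
    obj = np.asarray(m["obj"], dtype=float)
    lb = np.asarray(m["lb"], dtype=float)
    ub = np.asarray(m["ub"], dtype=float)
    vtype = m["vtype"]
    integrality = np.array([0 if t == "C" else 1 for t in vtype])
    ai = np.asarray(m["ai"], dtype=int) - 1
    aj = np.asarray(m["aj"], dtype=int) - 1
    ax = np.asarray(m["ax"], dtype=float)
    nrow = int(m["nrow"])
    lo = np.asarray(m["lo"], dtype=float)
    hi = np.asarray(m["hi"], dtype=float)
    def deinf(a):
        a = np.where(a >= 1e29, np.inf, a)
        return np.where(a <= -1e29, -np.inf, a)
    lo, hi, lb, ub = deinf(lo), deinf(hi), deinf(lb), deinf(ub)
    opts = {"presolve": True}
    if m.get("time_limit") is not None:
        opts["time_limit"] = float(m["time_limit"])
    if m.get("mip_rel_gap") is not None:
        opts["mip_rel_gap"] = float(m["mip_rel_gap"])
    cons = []
    if nrow > 0:
        A = csc_matrix((ax, (ai, aj)), shape=(nrow, n))
        cons = [LinearConstraint(A, lo, hi)]
    res = milp(c=obj, constraints=cons, integrality=integrality,
               bounds=Bounds(lb, ub), options=opts)
    out = {"status": int(res.status), "message": str(res.message),
           "success": bool(res.success)}
    if res.x is not None:
        x = np.asarray(res.x, dtype=float)
        ints = integrality == 1
        x[ints] = np.round(x[ints])
        out["x"] = x.tolist()
        out["objective"] = float(np.dot(obj, x)) + float(m.get("objconst", 0.0))
        gap = getattr(res, "mip_gap", None)
        out["gap"] = float(gap) if gap is not None else 0.0
    return out


def main():
    inp, outp = sys.argv[1], sys.argv[2]
    with open(inp) as fh:
        models = json.load(fh)
    res = [solve_one(m) for m in models]
    with open(outp, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
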