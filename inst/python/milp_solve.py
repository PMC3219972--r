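"""Batch MILP/LP solver backend (HiGHS via scipy.optimize.milp).

Reads a JSON file holding one or more problems in triplet form, solves each,
and writes a JSON file with one result per problem.  Invoked by the R facade;
not intended for interactive use.

Input schema (per problem):
  n            number of variables
  obj          list[n]   objective coefficients (minimized)
  lb, ub       list[n]   variable bounds ("inf"/-1e30 sentinels accepted)
  integrality  list[n]   0 = continuous, 1 = integer
  A            {"i": [...], "j": [...], "x": [...]}  1-based triplets
  cl, cu       list[m]   constraint lower/upper bounds
  time_limit   optional seconds

Output (per problem):
  status       one of optimal | infeasible | unbounded | limit | error
  objective    number or null
  x            list[n] or null
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "error"}

BIG = 1e30


def _list(v):
    """JSON length-1 arrays may arrive unboxed as scalars."""
    if v is None:
        return []
    if isinstance(v, (int, float)):
        return [v]
    return list(v)


def _vec(v, n, default):
    if v is None:
        return np.full(n, default, dtype=float)
    out = np.asarray([float(x) for x in _list(v)], dtype=float)
    out[out >= BIG] = np.inf
    out[out <= -BIG] = -np.inf
    return out


def solve_one(p):
    n = int(p["n"])
    c = np.asarray(_list(p["obj"]), dtype=float)
    lb = _vec(p.get("lb"), n, 0.0)
    ub = _vec(p.get("ub"), n, np.inf)
    integrality = np.asarray(_list(p.get("integrality")) or [0] * n,
                             dtype=int)

    constraints = []
    a = p.get("A") or {}
    m = len(_list(p.get("cl")))
    if m:
        rows = np.asarray(_list(a.get("i")), dtype=int) - 1
        cols = np.asarray(_list(a.get("j")), dtype=int) - 1
        vals = np.asarray(_list(a.get("x")), dtype=float)
        A = sparse.csc_matrix((vals, (rows, cols)), shape=(m, n))
        cl = _vec(p["cl"], m, -np.inf)
        cu = _vec(p["cu"], m, np.inf)
        constraints.append(LinearConstraint(A, cl, cu))

    options = {}
    if p.get("time_limit") is not None:
        options["time_limit"] = float(p["time_limit"])

    try:
        res = milp(
            c,
            constraints=constraints,
            integrality=integrality,
            bounds=Bounds(lb, ub),
            options=options,
        )
    except Exception as exc:  # defensive: report, never crash the batch
        return {"status": "error", "objective": None, "x": None,
                "message": str(exc)}

    status = STATUS.get(res.status, "error")
    if res.x is None and status == "optimal":
        status = "error"
    return {
        "status": status,
        "objective": None if res.fun is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
    }


def main(argv):
    if len(argv) != 3:
        sys.stderr.write("usage: milp_solve.py <in.json> <out.json>\n")
        return 2
    with open(argv[1]) as fh:
        payload = json.load(fh)
    problems = payload["problems"]
    results = [solve_one(p) for p in problems]
    with open(argv[2], "w") as fh:
        json.dump({"results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
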