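#!/usr/bin/env python
"""Optional: export neuron and edge tables from the hemibrain v1.2.1
connectome for use with flysnn::build_from_connectome().

Requires network access, a neuPrint auth token, and the neuprint-python
client (https://connectome-neuprint.github.io/neuprint-python/). Not used
by the package tests; the synthetic generator stands in when no export is
available.

Output: neurons.csv (id, class, glomerulus) and edges.csv
(pre_id, post_id, synapse_count), readable by read_neuron_table() /
read_edge_table().
"""

import os
import re
import sys

try:
    from neuprint import Client, NeuronCriteria, fetch_neurons, fetch_adjacencies
except ImportError:
    sys.exit("install neuprint-python first: pip install neuprint-python")

TOKEN = os.environ.get("NEUPRINT_TOKEN")
if not TOKEN:
    sys.exit("set NEUPRINT_TOKEN (https://neuprint.janelia.org account token)")

c = Client("neuprint.janelia.org", dataset="hemibrain:v1.2.1", token=TOKEN)

# Right-hemisphere olfactory populations by type/instance patterns. ORNs
# appear as ORN_<glomerulus>; uniglomerular PNs as <glomerulus>_*PN;
# LN connectivity is regenerated from innervation probabilities, so LN
# bodies are listed only for counting.
CRITERIA = {
    "ORN": NeuronCriteria(type="^ORN_.*", regex=True),
    "PN": NeuronCriteria(type=".*_(ad|l|il)?PN$", regex=True),
    "LN": NeuronCriteria(type="^(lLN|v2LN|vLN|il3LN|l2LN).*", regex=True),
    "KC": NeuronCriteria(type="^KC.*", regex=True),
    "APL": NeuronCriteria(type="^APL$", regex=True),
    "MBON_a1": NeuronCriteria(type="^MBON07.*", regex=True),  # MBON-alpha1
    "MBON_a3": NeuronCriteria(type="^MBON14.*", regex=True),  # MBON-alpha3
    "SMP354": NeuronCriteria(bodyId=390003153),
}

rows = []
all_ids = []
for cls, crit in CRITERIA.items():
    df, _ = fetch_neurons(crit)
    for _, r in df.iterrows():
        glom = None
        m = re.match(r"ORN_(\w+)", str(r.get("type") or ""))
        if m:
            glom = m.group(1)
        rows.append((r.bodyId, cls, glom or ""))
        all_ids.append(r.bodyId)

with open("neurons.csv", "w") as fh:
    fh.write("id,class,glomerulus\n")
    for i, cls, g in rows:
        fh.write(f"{i},{cls},{g}\n")

# pairwise connection counts among the selected bodies
_, conn = fetch_adjacencies(all_ids, all_ids)
conn = conn.groupby(["bodyId_pre", "bodyId_post"], as_index=False)["weight"].sum()
conn.rename(columns={"bodyId_pre": "pre_id", "bodyId_post": "post_id",
                     "weight": "synapse_count"}, inplace=True)
conn.to_csv("edges.csv", index=False)
print(f"wrote {len(rows)} neurons, {len(conn)} edges")
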