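<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for the BioC subset emitted by this package: collection >
     document > passage > annotation, with section carried as a passage
     infon and positions as location offset/length. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="collection">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="source" type="xs:string" minOccurs="0"/>
        <xs:element name="date" type="xs:string" minOccurs="0"/>
        <xs:element name="key" type="xs:string" minOccurs="0"/>
        <xs:element ref="infon" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element ref="document" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
  <xs:element name="infon">
    <xs:complexType>
      <xs:simpleContent>
        <xs:extension base="xs:string">
          <xs:attribute name="key" type="xs:string" use="required"/>
        </xs:extension>
      </xs:simpleContent>
    </xs:complexType>
  </xs:element>
  <xs:element name="document">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="id" type="xs:string"/>
        <xs:element ref="infon" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element ref="passage" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
  <xs:element name="passage">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="infon" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="offset" type="xs:nonNegativeInteger"/>
        <xs:element name="text" type="xs:string" minOccurs="0"/>
        <xs:element ref="annotation" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
  <xs:element name="annotation">
    <xs:complexType>
      <xs:sequence>
        <xs:element ref="infon" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="location" minOccurs="1" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="offset" type="xs:nonNegativeInteger" use="required"/>
            <xs:attribute name="length" type="xs:positiveInteger" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="text" type="xs:string" minOccurs="0"/>
      </xs:sequence>
      <xs:attribute name="id" type="xs:string"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
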